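subject_id,phenotype,body_weight
S1_RM,RM,65
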