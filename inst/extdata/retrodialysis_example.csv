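subject_id,catheter_id,occasion,replicate,retroperfusate_conc,retrodialysate_conc
S1_RM,C1,1,1,200,15.4
S1_RM,C1,1,2,200,14.9
S1_RM,C1,2,1,200,15.8
S1_RM,C1,2,2,200,16.1
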