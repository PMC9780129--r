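subject_id,analyte,catheter_id,interval_index,t_start,t_end,concentration
S1_RM,VRC,C1,1,0,0.5,0.31
S1_RM,VRC,C1,1,0.5,1,1.12
S1_RM,VRC,C1,1,11,12,0.95
S1_RM,NO,C1,1,11,12,1.73
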