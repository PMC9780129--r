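subject_id,analyte,interval_index,time,concentration
S1_RM,VRC,1,0,0
S1_RM,VRC,1,0.5,2.41
S1_RM,VRC,1,2,8.93
S1_RM,VRC,1,12,1.62
S1_RM,NO,1,2,1.05
S1_RM,NO,1,12,4.87
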