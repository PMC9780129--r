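subject_id,interval_index,start_time,amount,route,duration
S1_RM,1,0,390,iv_infusion,2
S1_RM,2,12,390,iv_infusion,2
S1_RM,3,24,260,iv_infusion,1.3
S1_RM,4,36,260,iv_infusion,1.3
S1_RM,5,48,200,oral,0
S1_RM,6,60,200,oral,0
S1_RM,7,72,200,oral,0
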