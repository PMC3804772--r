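compound_id,source,kd_mean,kd_sd
1,table1,152,1.0
1,abstract,144,1.0
1,conclusions,144,2.8
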