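roi,mean_obs1_gcm2,mean_obs2_gcm2,sd_obs1_gcm2,sd_obs2_gcm2,diff_printed_gcm2,pct_printed
total_hip,0.668,0.675,0.142,0.146,0.007,1.0
femoral_neck,0.585,0.578,0.121,0.118,-0.007,1.2
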