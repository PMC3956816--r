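roi,device,mean_bmd_gcm2,precision_sd_gcm2,cv_printed_pct
total_hip,CTXA,0.645,0.012,1.8
total_hip,DXA,0.700,0.014,2.0
femoral_neck,CTXA,0.551,0.011,2.0
femoral_neck,DXA,0.598,0.016,2.7
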