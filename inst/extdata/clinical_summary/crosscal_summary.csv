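roi,site,n,ctxa_mean,ctxa_sd,dxa_mean,dxa_sd,slope,intercept,r,see
total_hip,site1,30,0.657,0.143,0.766,0.138,0.988,-0.100,0.95,0.046
total_hip,site2,39,0.755,0.175,0.851,0.170,0.999,-0.094,0.97,0.043
total_hip,pooled,69,0.712,0.168,0.814,0.161,1.006,-0.106,0.97,0.044
femoral_neck,pooled,69,NA,NA,NA,NA,NA,NA,0.95,0.044
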