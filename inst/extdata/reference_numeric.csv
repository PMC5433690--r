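variable,stat,RFH,ALH,MALToma
age,mean,55.92,60.44,64.95
age,sd,12.85,12.99,12.16
age,min,13,23,35
age,max,82,77,93
duration_months,min,0.5,1,1
duration_months,max,360,120,240
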