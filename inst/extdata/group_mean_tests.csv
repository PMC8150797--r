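variable,wilks_lambda,F,df1,df2
P5,0.480,44.881,2,83
P7,0.776,11.946,2,83
P8,0.401,61.900,2,83
P10,0.550,34.005,2,83
P12,0.264,115.938,2,83
P14,0.383,66.762,2,83
P16,0.623,25.106,2,83
P17,0.246,127.075,2,83
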