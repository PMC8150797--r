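variable,function1,function2
P5,-0.303,0.333
P7,-0.184,0.110
P8,-0.326,0.437
P10,-0.202,0.371
P12,-0.475,0.555
P14,-0.368,0.409
P16,-0.185,0.306
P17,0.394,0.714
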