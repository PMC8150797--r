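sample_id,origin,P8,P12,P14,P17
B01,Korean,2.703,0.804,1.097,0.624
B02,Korean,2.637,0.749,1.081,0.794
B03,Korean,2.379,0.549,0.960,0.858
B04,Korean,1.328,0.414,0.712,0.808
B05,Korean,0.955,0.268,0.577,0.753
B06,Korean,1.562,0.465,0.709,0.729
B07,Korean,1.623,0.522,0.772,0.782
B08,Korean,2.393,0.781,0.912,0.873
B09,Korean,1.903,0.637,0.753,0.752
B10,Chinese,4.197,1.525,1.437,0.935
B11,Chinese,4.544,1.515,1.284,0.841
B12,Chinese,3.684,1.287,1.400,0.759
B13,Chinese,7.074,2.778,2.220,1.117
B14,Chinese,5.164,1.858,1.534,0.921
B15,Vietnamese,4.362,1.777,1.648,0.690
B16,Vietnamese,5.107,1.818,1.564,0.604
B17,Vietnamese,5.320,1.919,1.608,0.694
B18,Vietnamese,5.670,2.100,1.824,0.617
B19,Vietnamese,6.971,2.468,1.955,0.559
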