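label,wavenumber,functional_group,vibration_mode
P1,3010,=C-H (cis-),stretching
P2,2958,-C-H (CH3),stretching
P3,2924,-C-H (asym CH2),stretching
P4,2852,-C-H (sym CH2),stretching
P5,1745,-C=O (ester),stretching
P6,1653,-C=C- (cis-),stretching
P7,1516,-C-C- (aromatic),stretching
P8,1468,"-C-H (CH2, CH3)",bending
P9,1439,-C-H (CH2),bending
P10,1415,=C-H (cis-),bending
P11,1398,"-C-H (CH2, CH3)",bending
P12,1377,-C-H (CH3),bending
P13,1238,"-C-O (ester), -C-H (CH2)","stretching, bending"
P14,1159,-C-O (ester),stretching
P15,1142,-C-O,stretching
P16,1101,-C-O,stretching
P17,1053,-C-O,stretching
P18,1028,-C-O,stretching
P19,1008,-C-O,stretching
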