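haplotype,c80,c97,c161,c165,c195,c196,c254,c269,c289,c298,c448,c920,c944,c945,c946,c1004,c1035,c1062,c1124,c1150,c1285,c1372,c1375
H1,A,C,T,G,0,0,0,G,A,G,G,G,C,A,A,T,A,G,G,1,0,T,G
H2,A,C,T,G,0,0,0,G,A,A,G,G,C,A,A,T,A,G,G,1,0,T,G
H3,A,C,T,G,0,0,0,G,A,G,G,G,A,A,A,T,A,G,G,1,0,T,G
H4,A,C,T,G,0,0,0,G,A,G,G,A,C,A,A,T,A,G,G,1,0,T,G
H5,A,C,T,G,0,0,0,G,A,G,G,G,C,C,A,T,A,G,G,1,0,T,G
H6,A,C,T,G,0,0,0,G,A,G,G,G,C,C,C,T,A,G,G,1,0,T,G
H7,G,T,T,T,1,0,0,T,G,G,G,G,C,A,A,C,A,G,T,0,1,C,C
H8,G,T,T,T,1,0,1,T,G,G,G,G,C,A,A,C,A,G,T,0,1,C,C
H9,G,T,T,T,1,0,0,A,G,G,G,G,C,A,A,C,A,G,T,0,1,C,C
H10,G,T,T,T,1,1,0,A,G,G,G,G,A,A,A,C,A,G,T,0,1,C,C
H11,G,T,T,T,1,0,0,T,G,G,G,G,C,C,A,C,A,G,T,0,1,C,C
H12,G,T,T,T,1,0,0,T,G,G,G,G,C,C,A,C,A,C,T,0,1,C,C
H13,G,T,C,T,1,0,0,T,G,G,G,G,C,C,A,C,A,C,T,0,1,C,C
H14,G,T,T,T,1,0,0,T,G,G,G,G,C,C,C,C,A,C,T,0,1,C,C
H15,G,T,T,T,1,0,0,T,G,G,G,G,C,C,C,C,C,C,T,0,1,C,C
H16,G,T,T,T,1,0,0,T,G,G,A,G,C,C,A,C,A,C,T,0,1,C,C
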