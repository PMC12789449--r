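Block,Position,Coronal Deviation A (mm),Apical Deviation B (mm),Angle Error (Degrees)
1,a,0.76,0.50,2.22
1,b,0.43,0.41,1.15
1,c,0.53,0.43,1.00
1,d,0.55,0.41,3.06
2,a,0.55,0.25,2.19
2,b,0.47,0.19,2.32
2,c,0.54,0.38,2.11
2,d,0.62,0.50,2.58
3,a,0.34,0.23,2.15
3,b,0.36,0.33,0.69
3,c,0.32,0.16,1.38
3,d,0.11,0.16,0.21
4,a,0.23,0.31,2.26
4,b,0.33,0.14,1.40
4,c,0.28,0.09,1.59
4,d,0.60,0.36,4.62
5,a,0.36,0.09,2.27
5,b,0.64,0.17,3.35
5,c,0.44,0.18,1.44
5,d,0.57,0.31,1.83
6,a,1.03,1.13,1.97
6,b,2.59,1.75,6.96
6,c,1.21,1.45,2.25
6,d,2.84,1.56,7.25
7,a,1.89,0.70,6.40
7,b,1.38,1.10,2.40
7,c,0.92,0.92,0.31
7,d,1.29,0.67,3.24
8,a,0.72,0.54,1.23
8,b,1.01,0.68,2.24
8,c,0.73,0.54,1.13
8,d,0.73,0.69,1.61
9,a,0.98,0.61,3.81
9,b,1.07,0.93,2.58
9,c,1.45,1.53,1.37
9,d,1.08,0.67,3.53
10,a,0.28,0.31,1.41
10,b,0.84,0.64,1.34
10,c,1.28,0.81,3.34
10,d,1.14,0.65,3.00
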