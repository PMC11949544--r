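name	x	y	z
Fp1	-0.309	0.951	0
Fp2	0.309	0.951	0
F7	-0.809	0.588	0
F3	-0.545	0.673	0.5
Fz	0	0.707	0.707
F4	0.545	0.673	0.5
F8	0.809	0.588	0
T3	-1	0	0
C3	-0.707	0	0.707
Cz	0	0	1
C4	0.707	0	0.707
T4	1	0	0
T5	-0.809	-0.588	0
P3	-0.545	-0.673	0.5
Pz	0	-0.707	0.707
P4	0.545	-0.673	0.5
T6	0.809	-0.588	0
O1	-0.309	-0.951	0
O2	0.309	-0.951	0
Fpz	0	1	0
Oz	0	-1	0
AF3	-0.45	0.85	0.28
AF4	0.45	0.85	0.28
FC1	-0.35	0.37	0.86
FC2	0.35	0.37	0.86
FC5	-0.78	0.3	0.55
FC6	0.78	0.3	0.55
CP1	-0.35	-0.37	0.86
CP2	0.35	-0.37	0.86
CP5	-0.78	-0.3	0.55
CP6	0.78	-0.3	0.55
POz	0	-0.85	0.53
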