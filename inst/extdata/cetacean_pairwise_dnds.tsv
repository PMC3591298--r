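taxon_a	taxon_b	omega
S_whale	L_b_whale	0.2761
P_s_whale	L_b_whale	0.2259
P_s_whale	S_whale	0.2122
M_whale	L_b_whale	0.2647
M_whale	S_whale	0.2741
M_whale	P_s_whale	0.2735
M_h_whale	L_b_whale	0.2433
M_h_whale	S_whale	0.1950
M_h_whale	P_s_whale	0.1890
M_h_whale	M_whale	0.1754
P_b_whale	L_b_whale	0.3057
P_b_whale	S_whale	0.2324
P_b_whale	P_s_whale	0.2636
P_b_whale	M_whale	0.1566
P_b_whale	M_h_whale	0.2386
Sei_whale	L_b_whale	0.3469
Sei_whale	S_whale	0.2538
Sei_whale	P_s_whale	0.2832
Sei_whale	M_whale	0.1262
Sei_whale	M_h_whale	0.2173
Sei_whale	P_b_whale	0.001
S_b_whale	L_b_whale	0.1079
S_b_whale	S_whale	0.2641
S_b_whale	P_s_whale	0.2166
S_b_whale	M_whale	0.2796
S_b_whale	M_h_whale	0.2723
S_b_whale	P_b_whale	0.3261
S_b_whale	Sei_whale	0.3705
Dolphin	L_b_whale	0.2805
Dolphin	S_whale	0.2536
Dolphin	P_s_whale	0.2374
Dolphin	M_whale	0.2096
Dolphin	M_h_whale	0.3328
Dolphin	P_b_whale	0.2865
Dolphin	Sei_whale	0.2592
Dolphin	S_b_whale	0.3176
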