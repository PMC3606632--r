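gene_id	tphk_myc	tphk_pri	log2_ratio_printed
CC1G_02184T0	879.2	0.0	9.78
CC1G_07511T0	752.1	0.0	9.55
CC1G_08199T0	516.0	0.0	9.01
CC1G_08735T0	482.7	0.0	8.92
CC1G_11444T0	460.0	0.0	8.85
CC1G_12265T0	970.0	2.1	8.83
CC1G_02183T0	729.4	2.1	8.42
CC1G_13813T0	293.6	0.0	8.20
CC1G_07100T0	272.4	0.0	8.09
CC1G_10342T0	254.2	0.0	7.99
CC1G_11525T0	236.1	0.0	7.88
CC1G_00675T0	230.0	0.0	7.85
CC1G_07531T0	151.3	0.0	7.24
CC1G_04294T0	149.8	0.0	7.23
CC1G_12264T0	139.2	0.0	7.12
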