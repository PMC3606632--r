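gene_id	tphk_myc	tphk_pri	log2_ratio_printed
CC1G_05471T0	0.0	620.5	-9.28
CC1G_09700T0	0.0	530.8	-9.05
CC1G_03340T0	0.0	374.8	-8.55
CC1G_06766T0	0.0	244.6	-7.93
CC1G_04060T0	0.0	197.6	-7.63
CC1G_06484T0	0.0	147.4	-7.20
CC1G_11781T0	0.0	141.0	-7.14
CC1G_04061T0	0.0	104.7	-6.71
CC1G_01315T0	0.0	99.3	-6.63
CC1G_12474T0	0.0	83.3	-6.38
CC1G_03570T0	4.5	314.0	-6.11
CC1G_14841T0	0.0	66.2	-6.05
CC1G_01233T0	0.0	60.9	-5.93
CC1G_10308T0	0.0	57.7	-5.85
CC1G_14100T0	0.0	56.6	-5.82
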