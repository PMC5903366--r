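region	name	v_left_ul	v_right_ul	laterality_pct
Pu	Putamen	5224	5196	0.3
Ca	Caudate	4493	4543	-0.6
NAC	Nucleus Accumbens	397	399	-0.3
EXA	Extended Amygdala	134	136	-1.0
GPe	Globus Pallidus (External)	696	678	1.3
GPi	Globus Pallidus (Internal)	383	383	0.0
VeP	Ventral Pallidum	68	74	-4.3
SNc	Substantia Nigra (Compacta)	132	136	-1.5
SNr	Substantia Nigra (Reticulata)	261	269	-1.4
PBP	Parabrachial Pigmented Nucleus	99	98	0.5
STH	Subthalamic Nucleus	135	128	2.9
VTA	Ventral Tegmentum	33	33	0.1
HTH	Hypothalamus	604	617	-1.1
RN	Red Nucleus	301	298	0.5
MN	Mammillary Nucleus	64	62	2.0
HN	Habenular Nuclei	29	27	4.5
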