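label	mutation	t_half_57C	relative_activity
M0	I304L/F395V	2	100
M1	M0+D17V	40	105
M2-1	M1+L6P	142	104.76
M2-2	M1+T251C	71	118.09
M2-3	M1+K351E	101	161.90
M2-4	M1+T199S	210	111.43
M3-1	M2-4+T251C	599	112.38
M3-2	M2-4+F108Y	482	106.67
M3-3	M2-4+K351E	859	157.61
M3-4	M2-4+L6P	1258	123.81
M4-1	M3-4+F108Y	2498	134.28
M4-2	M3-4+T251C	3371	110.47
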