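label	mutation	t50_15	t50_se	tm	tm_se
M0	I304L/F395V	55.5	0.1	59.6	0.40
M1	M0+D17V	59.06	0.3	62.12	0.02
M2-4	M1+T199S	61.35	0.2	63.93	0.30
M3-4	M2-4+L6P	62.21	0.12	64.94	0.20
M4-1	M3-4+F108Y	61.0	0.15	64.35	0.31
M4-2	M3-4+T251C	59.7	0.1	64.24	0.23
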