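label	secondary_structure	active_site_distance	frequency_pct	t_half_55C	relative_activity
M0	NA	NA	NA	11.6	100
L6P	Loop	12.2	58.97	19	94.28
D17V	Loop	11.2	43.04	150	105.00
P20T	Loop	11.2	61.00	8.7	95.24
V33L	a-Helix	15.6	59.58	5.45	114.29
C52N	a-Helix	9.4	91.21	7.85	110.47
G58D	b-Turn	11.9	61.00	17	83.80
W59F	b-Turn	8	85.88	3	120.95
D73T	b-Turn	20.8	68.85	8.1	106.67
F108Y	a-Helix	7.8	71.10	16	105.00
Y109F	a-Helix	8.3	69.85	13	122.86
L162A	b-Turn	13.0	66.42	10.4	108.57
T117P	b-Turn	21.0	44.84	12	100.92
Q165I	a-Helix	9.8	60.03	20.7	88.57
K166A	a-Helix	10.2	51.51	11.3	103.81
T199S	a-Helix	10.2	42.81	14	117.14
T251C	b-Sheet	6.3	78.10	23	107.62
E349V	Loop	14.3	96.20	12	114.29
K351E	Loop	15.7	83.23	13.7	142.86
V362I	b-Sheet	6.8	48.15	10.9	99.05
V340L	Loop	6.2	66.40	3.8	80.00
C331S	Loop	6.2	83.72	6	121.90
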