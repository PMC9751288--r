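cell_type	d1_male	d1_male_pct	d3_male	d3_male_pct	d7_male	d7_male_pct	d1_female	d1_female_pct	expected_pct
R1-6	4079	37	3538	50	2460	49	3156	55	30
R7	1770	16	1251	18	953	19	965	17	5
R8	791	7.1	575	8.2	504	10	386	7.4	5
cone	28	0.25	56	0.80	24	0.48	0	0	20
pigment1	122	1.1	44	0.63	48	0.95	0	0	10
pigment23	4374	39	1551	22	1046	21	1219	21	20
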