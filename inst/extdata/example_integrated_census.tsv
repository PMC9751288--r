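cell_type	d1_male	d1_female	merged	merged_pct
R1-6	4150	3064	7214	43
R7	1739	997	2736	16
R8	803	449	1252	7.4
cone	32	6	38	0.22
pigment1	112	33	145	0.86
pigment23	4328	1177	5505	33
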