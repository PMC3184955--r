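aa	CA	HA	N	HN
A	53.18	4.24	123.23	8.20
C	58.26	4.67	120.01	8.39
D	54.69	4.59	120.69	8.31
E	57.34	4.25	120.68	8.33
F	58.09	4.61	120.38	8.36
G	45.35	3.97	109.62	8.33
H	56.52	4.60	119.03	8.25
I	61.62	4.17	121.47	8.26
K	56.94	4.26	121.04	8.22
L	55.65	4.31	121.83	8.21
M	56.12	4.41	120.08	8.27
N	53.55	4.66	118.91	8.34
P	63.36	4.40	135.83	8.41
Q	56.58	4.27	119.86	8.21
R	56.79	4.28	120.82	8.23
S	58.70	4.47	115.77	8.29
T	62.23	4.45	115.35	8.23
V	62.55	4.17	121.05	8.27
W	57.71	4.66	121.71	8.28
Y	58.14	4.60	120.47	8.32
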