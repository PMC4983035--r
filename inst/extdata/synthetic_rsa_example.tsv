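# synthetic RSA profile (constructed demonstration data, not predictor output)
pos	res	rsa
1	V	0.398
2	A	0.324
3	Q	0.232
4	F	0.533
5	N	0.372
6	C	0.249
7	I	0.458
8	R	0.490
9	G	0.517
10	G	0.461
11	A	0.129
12	S	0.221
13	F	0.072
14	F	0.082
15	I	0.180
16	V	0.215
17	V	0.333
18	G	0.259
19	F	0.173
20	A	0.091
21	N	0.135
22	A	0.136
23	I	0.264
24	I	0.229
25	F	0.171
26	A	0.377
27	S	0.360
28	I	0.150
29	K	0.517
30	T	0.151
31	T	0.348
32	K	0.248
33	W	0.450
34	R	0.206
35	Q	0.341
36	M	0.258
37	F	0.372
38	L	0.358
39	I	0.538
40	L	0.461
41	K	0.500
42	F	0.468
43	P	0.219
44	I	0.462
45	P	0.340
46	Y	0.420
47	R	0.291
48	G	0.392
49	D	0.724
50	D	0.741
51	D	0.378
52	D	0.480
53	E	0.376
54	E	0.301
55	E	0.449
56	D	0.352
57	E	0.575
58	E	0.675
59	D	0.616
60	E	0.353
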