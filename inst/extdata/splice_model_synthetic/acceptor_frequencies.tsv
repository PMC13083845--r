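pos	role	A	C	G	T
1	intron	0.11	0.30	0.10	0.49
2	intron	0.11	0.30	0.10	0.49
3	intron	0.11	0.30	0.10	0.49
4	intron	0.11	0.30	0.10	0.49
5	intron	0.11	0.30	0.10	0.49
6	intron	0.11	0.30	0.10	0.49
7	intron	0.09	0.31	0.08	0.52
8	intron	0.09	0.31	0.08	0.52
9	intron	0.09	0.31	0.08	0.52
10	intron	0.09	0.31	0.08	0.52
11	intron	0.08	0.33	0.07	0.52
12	intron	0.08	0.33	0.07	0.52
13	intron	0.08	0.33	0.07	0.52
14	intron	0.08	0.33	0.07	0.52
15	intron	0.07	0.38	0.06	0.49
16	intron	0.06	0.34	0.05	0.55
17	intron	0.23	0.29	0.21	0.27
18	intron	0.04	0.72	0.01	0.23
19	consensus	0.9903	0.0032	0.0035	0.0030
20	consensus	0.0027	0.0037	0.9906	0.0030
21	exon	0.24	0.14	0.52	0.10
22	exon	0.30	0.26	0.21	0.23
23	exon	0.24	0.26	0.26	0.24
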