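pos	role	A	C	G	T
1	exon	0.33	0.37	0.18	0.12
2	exon	0.60	0.13	0.13	0.14
3	exon	0.08	0.04	0.80	0.08
4	consensus	0.0040	0.0032	0.9896	0.0032
5	consensus	0.0034	0.0039	0.0042	0.9885
6	intron	0.59	0.03	0.36	0.02
7	intron	0.71	0.08	0.12	0.09
8	intron	0.06	0.05	0.84	0.05
9	intron	0.15	0.17	0.21	0.47
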