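position	A	C	G	T
-3	32	37	18	13
-2	60	13	12	15
-1	9	5	78	8
1	0	0	100	0
2	0	0	0	100
3	49	3	45	3
4	71	8	12	9
5	6	5	84	5
6	15	19	20	46
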