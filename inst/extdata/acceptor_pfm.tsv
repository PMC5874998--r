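position	A	C	G	T
-14	9	31	15	45
-13	9	33	13	45
-12	7	35	10	48
-11	8	35	10	47
-10	9	37	9	45
-9	6	38	9	47
-8	6	40	8	46
-7	7	40	8	45
-6	6	42	7	45
-5	6	45	6	43
-4	23	31	21	25
-3	2	64	1	33
-2	100	0	0	0
-1	0	0	100	0
1	25	15	50	10
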