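exon	inclusion_pct	inclusion_reads	exclusion_reads	skipping_events
12	54	147944	63724	10-13;10-14
13	79	194924	25860	10-14
37	98	335403	2848	36-38
48	2	5526	132355	47-50
52	98	222051	2319	51-54
53	98	252059	NA
79	99	262245	1287	c.22528-22871
86	91	174217	8333	85-88
87	93	216577	NA
113	90	187870	10267	112-114
117	92	200426	8651	116-119
118	92	209844	NA
133	66	66307	16926	132-134
138	97	143120	1865	137-143
139	96	86065	NA
140	95	77132	NA
141	96	97228	NA
142	96	100706	NA
145	83	82433	8300	144-146
147	62	86205	26227	c.33994-34301;146-151;146-152
148	68	72020	16913	146-151;146-152;147-149
149	67	53414	13407	146-151;146-152
150	4	3161	35240	146-151;146-152;149-151
151	94	94107	3145	146-152
154	82	115379	12300	153-158
155	35	52812	48202	153-158;154-158
156	34	49216	NA
157	40	64075	NA
159	20	52844	103121	158-167;158-168;158-171;158-172;158-173;158-175;158-182;158-184;158-191;158-193;158-204
167	2	6076	123699	158-168;158-171;158-172;158-173;158-175;158-182;158-184;158-191;158-193;158-204;159-168;159-171;159-172;159-173;159-175;159-184;159-193
168	7	16892	116748	158-171;158-172;158-173;158-175;158-182;158-184;158-191;158-193;158-204;159-168;159-171;159-172;159-173;159-175;159-184;159-193
169	6	14021	NA
170	4	9147	NA
171	5	11363	110061	158-172;158-173;158-175;158-182;158-184;158-191;158-193;158-204;159-172;159-173;159-175;159-184;159-193
206	81	184735	21799	175-209;184-209;c.38058-c.39484;193-209;c.39063-c.39484;203-209;c.39147-c.39484
207	68	91407	NA
208	76	86726	13717	175-209;184-209;193-209;203-209
209	97	99982	1741	208-210
213	26	37006	53547	212-218
214	17	22055	NA
215	22	29857	NA
216	19	26554	55194	212-218;215-217
217	19	24334	53547	212-218
220	99	168189	1146	219-222
221	99	194654	NA
225	95	124798	3126	224-226
244	93	285487	10706	c.44646-44914
363	91	115672	5458	362-364
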