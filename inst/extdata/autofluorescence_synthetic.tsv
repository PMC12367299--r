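# n_channels=256 cycle_ns=12.5
channel	count
0	43
1	42
2	41
3	40
4	39
5	38
6	37
7	36
8	35
9	34
10	33
11	32
12	32
13	32
14	37
15	55
16	108
17	250
18	582
19	1277
20	2567
21	4695
22	7813
23	11859
24	16492
25	21143
26	25178
27	28111
28	29744
29	30172
30	29689
31	28637
32	27312
33	25910
34	24543
35	23256
36	22065
37	20967
38	19956
39	19024
40	18163
41	17365
42	16625
43	15936
44	15294
45	14694
46	14132
47	13605
48	13109
49	12642
50	12201
51	11784
52	11388
53	11012
54	10655
55	10314
56	9989
57	9679
58	9382
59	9097
60	8824
61	8562
62	8310
63	8067
64	7834
65	7608
66	7391
67	7181
68	6978
69	6782
70	6593
71	6409
72	6231
73	6059
74	5892
75	5731
76	5574
77	5421
78	5274
79	5130
80	4991
81	4856
82	4725
83	4597
84	4473
85	4352
86	4235
87	4121
88	4011
89	3903
90	3798
91	3697
92	3598
93	3501
94	3408
95	3316
96	3228
97	3142
98	3058
99	2976
100	2897
101	2819
102	2744
103	2671
104	2600
105	2530
106	2463
107	2397
108	2333
109	2271
110	2211
111	2152
112	2094
113	2039
114	1984
115	1931
116	1880
117	1830
118	1781
119	1734
120	1688
121	1643
122	1599
123	1556
124	1515
125	1475
126	1435
127	1397
128	1360
129	1324
130	1288
131	1254
132	1221
133	1188
134	1157
135	1126
136	1096
137	1067
138	1038
139	1011
140	984
141	958
142	932
143	907
144	883
145	860
146	837
147	814
148	793
149	772
150	751
151	731
152	712
153	693
154	674
155	656
156	639
157	622
158	605
159	589
160	574
161	558
162	543
163	529
164	515
165	501
166	488
167	475
168	462
169	450
170	438
171	426
172	415
173	404
174	393
175	383
176	372
177	363
178	353
179	344
180	334
181	325
182	317
183	308
184	300
185	292
186	284
187	277
188	269
189	262
190	255
191	249
192	242
193	235
194	229
195	223
196	217
197	211
198	206
199	200
200	195
201	190
202	185
203	180
204	175
205	170
206	166
207	161
208	157
209	153
210	149
211	145
212	141
213	137
214	134
215	130
216	127
217	123
218	120
219	117
220	114
221	111
222	108
223	105
224	102
225	99
226	97
227	94
228	92
229	89
230	87
231	84
232	82
233	80
234	78
235	76
236	74
237	72
238	70
239	68
240	66
241	65
242	63
243	61
244	59
245	58
246	56
247	55
248	53
249	52
250	51
251	49
252	48
253	47
254	45
255	44
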