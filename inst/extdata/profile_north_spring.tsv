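depth	temperature	salinity
0	25	39.5
1	25	39.5
2	25	39.5
3	25	39.5
4	25	39.5
5	25	39.5
6	25	39.5
7	25	39.5
8	25	39.5
9	25	39.5
10	25	39.5
11	25	39.5
12	25	39.5
13	25	39.5
14	25	39.5
15	25	39.5
16	25	39.5
17	25	39.5
18	25	39.5
19	25	39.5
20	25	39.5
21	25	39.5
22	25	39.5
23	25	39.5
24	25	39.5
25	25	39.5
26	25	39.5
27	25	39.5
28	25	39.5
29	25	39.5
30	25	39.5
31	25	39.5
32	25	39.5
33	25	39.5
34	25	39.5
35	25	39.5
36	25	39.5
37	25	39.5
38	25	39.5
39	25	39.5
40	25	39.5
41	25	39.5
42	25	39.5
43	25	39.5
44	25	39.5
45	25	39.5
46	25	39.5
47	25	39.5
48	25	39.5
49	25	39.5
50	25	39.5
51	25	39.5
52	25	39.5
53	25	39.5
54	25	39.5
55	25	39.5
56	25	39.5
57	25	39.5
58	25	39.5
59	25	39.5
60	25	39.5
61	25	39.5
62	25	39.5
63	25	39.5
64	25	39.5
65	25	39.5
66	25	39.5
67	25	39.5
68	25	39.5
69	25	39.5
70	25	39.5
71	25	39.5
72	25	39.5
73	25	39.5
74	25	39.5
75	25	39.5
76	25	39.5
77	25	39.5
78	25	39.5
79	25	39.5
80	25	39.5
81	25	39.5
82	25	39.5
83	25	39.5
84	25	39.5
85	23.75	39.85
86	22.5	40.2
87	22.49122807017544	40.2
88	22.482456140350877	40.2
89	22.473684210526315	40.2
90	22.464912280701753	40.2
91	22.45614035087719	40.2
92	22.44736842105263	40.2
93	22.43859649122807	40.2
94	22.42982456140351	40.2
95	22.42105263157895	40.2
96	22.412280701754387	40.2
97	22.403508771929825	40.2
98	22.394736842105264	40.2
99	22.385964912280702	40.2
100	22.37719298245614	40.2
101	22.36842105263158	40.2
102	22.359649122807017	40.2
103	22.350877192982455	40.2
104	22.342105263157894	40.2
105	22.333333333333332	40.2
106	22.32456140350877	40.2
107	22.31578947368421	40.2
108	22.30701754385965	40.2
109	22.29824561403509	40.2
110	22.289473684210527	40.2
111	22.280701754385966	40.2
112	22.271929824561404	40.2
113	22.263157894736842	40.2
114	22.25438596491228	40.2
115	22.24561403508772	40.2
116	22.236842105263158	40.2
117	22.228070175438596	40.2
118	22.219298245614034	40.2
119	22.210526315789473	40.2
120	22.20175438596491	40.2
121	22.19298245614035	40.2
122	22.18421052631579	40.2
123	22.17543859649123	40.2
124	22.166666666666668	40.2
125	22.157894736842106	40.2
126	22.149122807017545	40.2
127	22.140350877192983	40.2
128	22.13157894736842	40.2
129	22.12280701754386	40.2
130	22.114035087719298	40.2
131	22.105263157894736	40.2
132	22.096491228070175	40.2
133	22.087719298245613	40.2
134	22.07894736842105	40.2
135	22.07017543859649	40.2
136	22.06140350877193	40.2
137	22.05263157894737	40.2
138	22.04385964912281	40.2
139	22.035087719298247	40.2
140	22.026315789473685	40.2
141	22.017543859649123	40.2
142	22.00877192982456	40.2
143	22	40.2
144	21.99122807017544	40.2
145	21.982456140350877	40.2
146	21.973684210526315	40.2
147	21.964912280701753	40.2
148	21.95614035087719	40.2
149	21.94736842105263	40.2
150	21.93859649122807	40.2
151	21.92982456140351	40.2
152	21.92105263157895	40.2
153	21.912280701754387	40.2
154	21.903508771929825	40.2
155	21.894736842105264	40.2
156	21.885964912280702	40.2
157	21.87719298245614	40.2
158	21.86842105263158	40.2
159	21.859649122807017	40.2
160	21.850877192982455	40.2
161	21.842105263157894	40.2
162	21.833333333333332	40.2
163	21.82456140350877	40.2
164	21.81578947368421	40.2
165	21.80701754385965	40.2
166	21.79824561403509	40.2
167	21.789473684210527	40.2
168	21.780701754385966	40.2
169	21.771929824561404	40.2
170	21.763157894736842	40.2
171	21.75438596491228	40.2
172	21.74561403508772	40.2
173	21.736842105263158	40.2
174	21.728070175438596	40.2
175	21.719298245614034	40.2
176	21.710526315789473	40.2
177	21.70175438596491	40.2
178	21.69298245614035	40.2
179	21.68421052631579	40.2
180	21.67543859649123	40.2
181	21.666666666666668	40.2
182	21.657894736842106	40.2
183	21.649122807017545	40.2
184	21.640350877192983	40.2
185	21.63157894736842	40.2
186	21.62280701754386	40.2
187	21.614035087719298	40.2
188	21.605263157894736	40.2
189	21.596491228070175	40.2
190	21.587719298245613	40.2
191	21.57894736842105	40.2
192	21.57017543859649	40.2
193	21.56140350877193	40.2
194	21.55263157894737	40.2
195	21.54385964912281	40.2
196	21.535087719298247	40.2
197	21.526315789473685	40.2
198	21.517543859649123	40.2
199	21.50877192982456	40.2
200	21.5	40.2
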