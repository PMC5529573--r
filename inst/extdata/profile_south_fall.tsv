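depth	temperature	salinity
0	32	37
1	32	37
2	32	37
3	32	37
4	32	37
5	32	37
6	32	37
7	32	37
8	32	37
9	32	37
10	32	37
11	32	37
12	32	37
13	32	37
14	32	37
15	32	37
16	29.5	37.75
17	27	38.5
18	26.994535519125684	38.5
19	26.989071038251367	38.5
20	26.983606557377048	38.5
21	26.97814207650273	38.5
22	26.972677595628415	38.5
23	26.9672131147541	38.5
24	26.961748633879782	38.5
25	26.956284153005466	38.5
26	26.950819672131146	38.5
27	26.94535519125683	38.5
28	26.939890710382514	38.5
29	26.934426229508198	38.5
30	26.92896174863388	38.5
31	26.92349726775956	38.5
32	26.918032786885245	38.5
33	26.91256830601093	38.5
34	26.907103825136613	38.5
35	26.901639344262296	38.5
36	26.896174863387976	38.5
37	26.89071038251366	38.5
38	26.885245901639344	38.5
39	26.879781420765028	38.5
40	26.87431693989071	38.5
41	26.868852459016395	38.5
42	26.863387978142075	38.5
43	26.85792349726776	38.5
44	26.852459016393443	38.5
45	26.846994535519126	38.5
46	26.84153005464481	38.5
47	26.83606557377049	38.5
48	26.830601092896174	38.5
49	26.825136612021858	38.5
50	26.81967213114754	38.5
51	26.814207650273225	38.5
52	26.80874316939891	38.5
53	26.80327868852459	38.5
54	26.797814207650273	38.5
55	26.792349726775956	38.5
56	26.78688524590164	38.5
57	26.781420765027324	38.5
58	26.775956284153004	38.5
59	26.770491803278688	38.5
60	26.76502732240437	38.5
61	26.759562841530055	38.5
62	26.75409836065574	38.5
63	26.74863387978142	38.5
64	26.743169398907103	38.5
65	26.737704918032787	38.5
66	26.73224043715847	38.5
67	26.726775956284154	38.5
68	26.721311475409838	38.5
69	26.715846994535518	38.5
70	26.7103825136612	38.5
71	26.704918032786885	38.5
72	26.69945355191257	38.5
73	26.693989071038253	38.5
74	26.688524590163933	38.5
75	26.683060109289617	38.5
76	26.6775956284153	38.5
77	26.672131147540984	38.5
78	26.666666666666668	38.5
79	26.661202185792348	38.5
80	26.65573770491803	38.5
81	26.650273224043715	38.5
82	26.6448087431694	38.5
83	26.639344262295083	38.5
84	26.633879781420767	38.5
85	26.628415300546447	38.5
86	26.62295081967213	38.5
87	26.617486338797814	38.5
88	26.612021857923498	38.5
89	26.60655737704918	38.5
90	26.601092896174862	38.5
91	26.595628415300546	38.5
92	26.59016393442623	38.5
93	26.584699453551913	38.5
94	26.579234972677597	38.5
95	26.57377049180328	38.5
96	26.56830601092896	38.5
97	26.562841530054644	38.5
98	26.557377049180328	38.5
99	26.55191256830601	38.5
100	26.546448087431695	38.5
101	26.540983606557376	38.5
102	26.53551912568306	38.5
103	26.530054644808743	38.5
104	26.524590163934427	38.5
105	26.51912568306011	38.5
106	26.51366120218579	38.5
107	26.508196721311474	38.5
108	26.502732240437158	38.5
109	26.497267759562842	38.5
110	26.491803278688526	38.5
111	26.48633879781421	38.5
112	26.48087431693989	38.5
113	26.475409836065573	38.5
114	26.469945355191257	38.5
115	26.46448087431694	38.5
116	26.459016393442624	38.5
117	26.453551912568305	38.5
118	26.44808743169399	38.5
119	26.442622950819672	38.5
120	26.437158469945356	38.5
121	26.43169398907104	38.5
122	26.42622950819672	38.5
123	26.420765027322403	38.5
124	26.415300546448087	38.5
125	26.40983606557377	38.5
126	26.404371584699454	38.5
127	26.398907103825138	38.5
128	26.39344262295082	38.5
129	26.387978142076502	38.5
130	26.382513661202186	38.5
131	26.37704918032787	38.5
132	26.371584699453553	38.5
133	26.366120218579233	38.5
134	26.360655737704917	38.5
135	26.3551912568306	38.5
136	26.349726775956285	38.5
137	26.34426229508197	38.5
138	26.338797814207652	38.5
139	26.333333333333332	38.5
140	26.327868852459016	38.5
141	26.3224043715847	38.5
142	26.316939890710383	38.5
143	26.311475409836067	38.5
144	26.306010928961747	38.5
145	26.30054644808743	38.5
146	26.295081967213115	38.5
147	26.2896174863388	38.5
148	26.284153005464482	38.5
149	26.278688524590162	38.5
150	26.273224043715846	38.5
151	26.26775956284153	38.5
152	26.262295081967213	38.5
153	26.256830601092897	38.5
154	26.25136612021858	38.5
155	26.24590163934426	38.5
156	26.240437158469945	38.5
157	26.23497267759563	38.5
158	26.229508196721312	38.5
159	26.224043715846996	38.5
160	26.218579234972676	38.5
161	26.21311475409836	38.5
162	26.207650273224044	38.5
163	26.202185792349727	38.5
164	26.19672131147541	38.5
165	26.19125683060109	38.5
166	26.185792349726775	38.5
167	26.18032786885246	38.5
168	26.174863387978142	38.5
169	26.169398907103826	38.5
170	26.16393442622951	38.5
171	26.15846994535519	38.5
172	26.153005464480874	38.5
173	26.147540983606557	38.5
174	26.14207650273224	38.5
175	26.136612021857925	38.5
176	26.131147540983605	38.5
177	26.12568306010929	38.5
178	26.120218579234972	38.5
179	26.114754098360656	38.5
180	26.10928961748634	38.5
181	26.103825136612024	38.5
182	26.098360655737704	38.5
183	26.092896174863387	38.5
184	26.08743169398907	38.5
185	26.081967213114755	38.5
186	26.07650273224044	38.5
187	26.07103825136612	38.5
188	26.065573770491802	38.5
189	26.060109289617486	38.5
190	26.05464480874317	38.5
191	26.049180327868854	38.5
192	26.043715846994537	38.5
193	26.038251366120218	38.5
194	26.0327868852459	38.5
195	26.027322404371585	38.5
196	26.02185792349727	38.5
197	26.016393442622952	38.5
198	26.010928961748633	38.5
199	26.005464480874316	38.5
200	26	38.5
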