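depth	temperature	salinity
0	27	39.5
1	27	39.5
2	27	39.5
3	27	39.5
4	27	39.5
5	27	39.5
6	27	39.5
7	27	39.5
8	27	39.5
9	27	39.5
10	27	39.5
11	25.5	39.85
12	24	40.2
13	23.99468085106383	40.2
14	23.98936170212766	40.2
15	23.98404255319149	40.2
16	23.97872340425532	40.2
17	23.97340425531915	40.2
18	23.96808510638298	40.2
19	23.96276595744681	40.2
20	23.95744680851064	40.2
21	23.95212765957447	40.2
22	23.9468085106383	40.2
23	23.94148936170213	40.2
24	23.93617021276596	40.2
25	23.930851063829788	40.2
26	23.925531914893618	40.2
27	23.920212765957448	40.2
28	23.914893617021278	40.2
29	23.909574468085108	40.2
30	23.904255319148938	40.2
31	23.898936170212767	40.2
32	23.893617021276597	40.2
33	23.888297872340427	40.2
34	23.882978723404257	40.2
35	23.877659574468087	40.2
36	23.872340425531913	40.2
37	23.867021276595743	40.2
38	23.861702127659573	40.2
39	23.856382978723403	40.2
40	23.851063829787233	40.2
41	23.845744680851062	40.2
42	23.840425531914892	40.2
43	23.835106382978722	40.2
44	23.829787234042552	40.2
45	23.824468085106382	40.2
46	23.819148936170212	40.2
47	23.81382978723404	40.2
48	23.80851063829787	40.2
49	23.8031914893617	40.2
50	23.79787234042553	40.2
51	23.79255319148936	40.2
52	23.78723404255319	40.2
53	23.78191489361702	40.2
54	23.77659574468085	40.2
55	23.77127659574468	40.2
56	23.76595744680851	40.2
57	23.76063829787234	40.2
58	23.75531914893617	40.2
59	23.75	40.2
60	23.74468085106383	40.2
61	23.73936170212766	40.2
62	23.73404255319149	40.2
63	23.72872340425532	40.2
64	23.72340425531915	40.2
65	23.71808510638298	40.2
66	23.71276595744681	40.2
67	23.70744680851064	40.2
68	23.70212765957447	40.2
69	23.6968085106383	40.2
70	23.69148936170213	40.2
71	23.68617021276596	40.2
72	23.680851063829788	40.2
73	23.675531914893618	40.2
74	23.670212765957448	40.2
75	23.664893617021278	40.2
76	23.659574468085108	40.2
77	23.654255319148938	40.2
78	23.648936170212767	40.2
79	23.643617021276597	40.2
80	23.638297872340427	40.2
81	23.632978723404257	40.2
82	23.627659574468087	40.2
83	23.622340425531913	40.2
84	23.617021276595743	40.2
85	23.611702127659573	40.2
86	23.606382978723403	40.2
87	23.601063829787233	40.2
88	23.595744680851062	40.2
89	23.590425531914892	40.2
90	23.585106382978722	40.2
91	23.579787234042552	40.2
92	23.574468085106382	40.2
93	23.569148936170212	40.2
94	23.56382978723404	40.2
95	23.55851063829787	40.2
96	23.5531914893617	40.2
97	23.54787234042553	40.2
98	23.54255319148936	40.2
99	23.53723404255319	40.2
100	23.53191489361702	40.2
101	23.52659574468085	40.2
102	23.52127659574468	40.2
103	23.51595744680851	40.2
104	23.51063829787234	40.2
105	23.50531914893617	40.2
106	23.5	40.2
107	23.49468085106383	40.2
108	23.48936170212766	40.2
109	23.48404255319149	40.2
110	23.47872340425532	40.2
111	23.47340425531915	40.2
112	23.46808510638298	40.2
113	23.46276595744681	40.2
114	23.45744680851064	40.2
115	23.45212765957447	40.2
116	23.4468085106383	40.2
117	23.44148936170213	40.2
118	23.43617021276596	40.2
119	23.430851063829788	40.2
120	23.425531914893618	40.2
121	23.420212765957448	40.2
122	23.414893617021278	40.2
123	23.409574468085108	40.2
124	23.404255319148938	40.2
125	23.398936170212767	40.2
126	23.393617021276597	40.2
127	23.388297872340427	40.2
128	23.382978723404257	40.2
129	23.377659574468083	40.2
130	23.372340425531917	40.2
131	23.367021276595743	40.2
132	23.361702127659573	40.2
133	23.356382978723403	40.2
134	23.351063829787233	40.2
135	23.345744680851062	40.2
136	23.340425531914892	40.2
137	23.335106382978722	40.2
138	23.329787234042552	40.2
139	23.324468085106382	40.2
140	23.319148936170212	40.2
141	23.31382978723404	40.2
142	23.30851063829787	40.2
143	23.3031914893617	40.2
144	23.29787234042553	40.2
145	23.29255319148936	40.2
146	23.28723404255319	40.2
147	23.28191489361702	40.2
148	23.27659574468085	40.2
149	23.27127659574468	40.2
150	23.26595744680851	40.2
151	23.26063829787234	40.2
152	23.25531914893617	40.2
153	23.25	40.2
154	23.24468085106383	40.2
155	23.23936170212766	40.2
156	23.23404255319149	40.2
157	23.22872340425532	40.2
158	23.22340425531915	40.2
159	23.21808510638298	40.2
160	23.21276595744681	40.2
161	23.20744680851064	40.2
162	23.20212765957447	40.2
163	23.1968085106383	40.2
164	23.19148936170213	40.2
165	23.18617021276596	40.2
166	23.180851063829788	40.2
167	23.175531914893618	40.2
168	23.170212765957448	40.2
169	23.164893617021278	40.2
170	23.159574468085108	40.2
171	23.154255319148938	40.2
172	23.148936170212767	40.2
173	23.143617021276597	40.2
174	23.138297872340427	40.2
175	23.132978723404257	40.2
176	23.127659574468083	40.2
177	23.122340425531917	40.2
178	23.117021276595743	40.2
179	23.111702127659573	40.2
180	23.106382978723403	40.2
181	23.101063829787233	40.2
182	23.095744680851062	40.2
183	23.090425531914892	40.2
184	23.085106382978722	40.2
185	23.079787234042552	40.2
186	23.074468085106382	40.2
187	23.069148936170212	40.2
188	23.06382978723404	40.2
189	23.05851063829787	40.2
190	23.0531914893617	40.2
191	23.04787234042553	40.2
192	23.04255319148936	40.2
193	23.03723404255319	40.2
194	23.03191489361702	40.2
195	23.02659574468085	40.2
196	23.02127659574468	40.2
197	23.01595744680851	40.2
198	23.01063829787234	40.2
199	23.00531914893617	40.2
200	23	40.2
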