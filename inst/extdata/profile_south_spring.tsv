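depth	temperature	salinity
0	30	37.5
1	30	37.5
2	30	37.5
3	30	37.5
4	30	37.5
5	30	37.5
6	30	37.5
7	30	37.5
8	30	37.5
9	30	37.5
10	30	37.5
11	30	37.5
12	30	37.5
13	30	37.5
14	30	37.5
15	30	37.5
16	30	37.5
17	30	37.5
18	30	37.5
19	30	37.5
20	30	37.5
21	30	37.5
22	30	37.5
23	30	37.5
24	30	37.5
25	30	37.5
26	30	37.5
27	30	37.5
28	30	37.5
29	30	37.5
30	30	37.5
31	30	37.5
32	30	37.5
33	30	37.5
34	30	37.5
35	30	37.5
36	30	37.5
37	30	37.5
38	30	37.5
39	30	37.5
40	30	37.5
41	30	37.5
42	30	37.5
43	30	37.5
44	30	37.5
45	30	37.5
46	30	37.5
47	30	37.5
48	30	37.5
49	30	37.5
50	30	37.5
51	28	38
52	26	38.5
53	25.993243243243242	38.5
54	25.986486486486488	38.5
55	25.97972972972973	38.5
56	25.972972972972972	38.5
57	25.966216216216218	38.5
58	25.95945945945946	38.5
59	25.9527027027027	38.5
60	25.945945945945947	38.5
61	25.93918918918919	38.5
62	25.93243243243243	38.5
63	25.925675675675677	38.5
64	25.91891891891892	38.5
65	25.91216216216216	38.5
66	25.905405405405407	38.5
67	25.89864864864865	38.5
68	25.89189189189189	38.5
69	25.885135135135137	38.5
70	25.87837837837838	38.5
71	25.87162162162162	38.5
72	25.864864864864863	38.5
73	25.85810810810811	38.5
74	25.85135135135135	38.5
75	25.844594594594593	38.5
76	25.83783783783784	38.5
77	25.83108108108108	38.5
78	25.824324324324323	38.5
79	25.81756756756757	38.5
80	25.81081081081081	38.5
81	25.804054054054053	38.5
82	25.7972972972973	38.5
83	25.79054054054054	38.5
84	25.783783783783782	38.5
85	25.777027027027028	38.5
86	25.77027027027027	38.5
87	25.763513513513512	38.5
88	25.756756756756758	38.5
89	25.75	38.5
90	25.743243243243242	38.5
91	25.736486486486488	38.5
92	25.72972972972973	38.5
93	25.722972972972972	38.5
94	25.716216216216218	38.5
95	25.70945945945946	38.5
96	25.7027027027027	38.5
97	25.695945945945947	38.5
98	25.68918918918919	38.5
99	25.68243243243243	38.5
100	25.675675675675677	38.5
101	25.66891891891892	38.5
102	25.66216216216216	38.5
103	25.655405405405407	38.5
104	25.64864864864865	38.5
105	25.64189189189189	38.5
106	25.635135135135137	38.5
107	25.62837837837838	38.5
108	25.62162162162162	38.5
109	25.614864864864863	38.5
110	25.60810810810811	38.5
111	25.60135135135135	38.5
112	25.594594594594593	38.5
113	25.58783783783784	38.5
114	25.58108108108108	38.5
115	25.574324324324323	38.5
116	25.56756756756757	38.5
117	25.56081081081081	38.5
118	25.554054054054053	38.5
119	25.5472972972973	38.5
120	25.54054054054054	38.5
121	25.533783783783782	38.5
122	25.527027027027028	38.5
123	25.52027027027027	38.5
124	25.513513513513512	38.5
125	25.506756756756758	38.5
126	25.5	38.5
127	25.493243243243242	38.5
128	25.486486486486488	38.5
129	25.47972972972973	38.5
130	25.472972972972972	38.5
131	25.466216216216218	38.5
132	25.45945945945946	38.5
133	25.4527027027027	38.5
134	25.445945945945947	38.5
135	25.43918918918919	38.5
136	25.43243243243243	38.5
137	25.425675675675677	38.5
138	25.41891891891892	38.5
139	25.41216216216216	38.5
140	25.405405405405407	38.5
141	25.39864864864865	38.5
142	25.39189189189189	38.5
143	25.385135135135137	38.5
144	25.37837837837838	38.5
145	25.37162162162162	38.5
146	25.364864864864863	38.5
147	25.35810810810811	38.5
148	25.35135135135135	38.5
149	25.344594594594593	38.5
150	25.33783783783784	38.5
151	25.33108108108108	38.5
152	25.324324324324323	38.5
153	25.31756756756757	38.5
154	25.31081081081081	38.5
155	25.304054054054053	38.5
156	25.2972972972973	38.5
157	25.29054054054054	38.5
158	25.283783783783782	38.5
159	25.277027027027028	38.5
160	25.27027027027027	38.5
161	25.263513513513512	38.5
162	25.256756756756758	38.5
163	25.25	38.5
164	25.243243243243242	38.5
165	25.236486486486488	38.5
166	25.22972972972973	38.5
167	25.222972972972972	38.5
168	25.216216216216218	38.5
169	25.20945945945946	38.5
170	25.2027027027027	38.5
171	25.195945945945947	38.5
172	25.18918918918919	38.5
173	25.18243243243243	38.5
174	25.175675675675677	38.5
175	25.16891891891892	38.5
176	25.16216216216216	38.5
177	25.155405405405407	38.5
178	25.14864864864865	38.5
179	25.14189189189189	38.5
180	25.135135135135137	38.5
181	25.12837837837838	38.5
182	25.12162162162162	38.5
183	25.114864864864863	38.5
184	25.10810810810811	38.5
185	25.10135135135135	38.5
186	25.094594594594593	38.5
187	25.08783783783784	38.5
188	25.08108108108108	38.5
189	25.074324324324323	38.5
190	25.06756756756757	38.5
191	25.06081081081081	38.5
192	25.054054054054053	38.5
193	25.0472972972973	38.5
194	25.04054054054054	38.5
195	25.033783783783782	38.5
196	25.027027027027028	38.5
197	25.02027027027027	38.5
198	25.013513513513512	38.5
199	25.006756756756758	38.5
200	25	38.5
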