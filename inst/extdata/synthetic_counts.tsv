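#OTU ID	sample_001	sample_002	sample_003	sample_004	sample_005	sample_006	sample_007	sample_008	sample_009	sample_010	sample_011	sample_012	sample_013	sample_014	sample_015	sample_016	sample_017	sample_018	sample_019	sample_020	sample_021	sample_022	sample_023	sample_024
syn_up	411	291	25	68	85	210	84	66	48	44	157	409	57	279	27	445	107	103	258	74	82	50	31	417
sar11_down	27	51	424	167	150	82	154	207	291	348	113	31	310	41	508	27	144	136	61	201	175	259	434	32
bathy_mid	27	75	32	114	97	109	107	92	50	25	114	28	59	46	23	38	124	102	82	104	127	56	28	32
proch_bimodal	192	775	717	335	324	1266	257	815	2442	2189	338	233	2454	650	327	217	261	246	1140	678	359	2216	693	224
cosmo_flat	123	134	126	109	109	125	106	114	112	125	110	126	134	132	101	135	116	112	115	124	108	120	119	128
bg_001	0	0	0	0	0	0	8	0	0	0	0	9	0	0	0	0	0	0	0	0	0	0	0	0
bg_002	14	19	0	0	0	0	17	21	17	0	18	22	14	0	13	29	0	0	0	19	18	22	18	15
bg_003	0	2	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
bg_004	0	0	0	0	0	0	0	0	0	0	0	0	43	0	0	0	0	0	0	0	0	0	0	0
bg_005	36	0	29	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	28	24	0	0	0	0
bg_006	0	20	0	0	30	0	0	0	26	0	30	0	25	0	0	0	0	0	0	0	0	0	0	0
bg_007	14	0	0	0	20	16	0	0	0	24	18	21	0	0	0	0	0	0	17	0	0	0	0	0
bg_008	0	0	0	0	0	0	0	0	0	0	0	0	6	0	0	0	0	0	0	0	0	0	0	0
bg_009	0	0	0	0	20	0	0	0	0	0	0	15	0	0	0	0	0	0	0	0	0	0	0	0
bg_010	56	0	0	0	0	0	56	0	0	0	0	0	0	0	0	0	0	0	54	0	0	52	0	62
bg_011	0	0	0	39	0	0	0	0	0	0	0	0	0	0	0	0	0	27	0	0	0	0	0	0
bg_012	0	0	0	0	0	0	0	8	0	0	0	0	0	0	0	0	0	0	0	11	0	0	10	0
bg_013	9	0	0	0	0	0	4	0	0	0	4	4	3	5	0	0	0	0	0	0	0	4	8	5
bg_014	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	2	0	0	0	1	0
bg_015	0	9	0	0	0	0	0	0	2	6	4	0	5	7	0	0	0	6	4	0	0	0	0	8
bg_016	0	0	0	0	9	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
bg_017	0	1	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	2	0	0	0	0	0	0
bg_018	50	0	0	0	0	0	0	0	0	0	0	44	0	0	0	0	33	0	0	0	0	51	0	0
bg_019	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
bg_020	0	0	15	0	0	0	0	0	0	11	0	0	0	0	0	0	0	0	0	12	0	0	0	0
bg_021	0	0	0	0	17	25	0	0	0	0	0	13	0	0	0	0	0	0	0	0	0	0	0	16
bg_022	0	0	0	0	0	0	0	0	0	0	7	5	0	0	0	0	7	0	6	0	0	4	0	6
bg_023	0	0	0	0	0	0	0	3	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0
bg_024	5	0	0	3	3	1	3	0	0	1	0	0	2	0	6	1	2	0	4	0	0	0	0	3
bg_025	0	3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	7
bg_026	0	0	0	0	0	0	0	0	0	0	0	0	0	0	4	0	7	0	6	8	0	0	0	0
bg_027	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	9	0	0	0	0	0	0	0	0
bg_028	12	0	0	0	0	0	13	0	7	0	0	9	0	0	0	0	0	0	12	0	11	11	12	12
bg_029	0	0	22	0	0	0	24	0	0	0	0	0	0	0	0	0	25	22	0	0	0	15	0	20
bg_030	62	0	0	48	0	52	75	71	0	0	0	60	0	0	0	0	0	61	0	0	0	0	62	49
bg_031	41	33	22	0	33	28	0	0	0	0	32	44	0	27	0	0	0	0	24	0	27	38	27	14
bg_032	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
bg_033	0	0	0	0	0	0	3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
bg_034	0	5	0	0	0	0	7	0	5	0	5	0	6	7	6	0	8	0	0	9	9	0	11	0
bg_035	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	20	0
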