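sample_id	region	season	depth_layer	depth	temperature	salinity	nitrate	nitrite	phosphate	silicate
sample_001	north	fall	dcm	74.43967526778579	33.07982658408582	39.58677429240197	1.5913702312402167	0.08016419394887024	0.0836690598756047	1.303033331886374
sample_002	north	spring	surface	8.764963084831834	31.54863713681698	36.930146559141576	0.27083143117845293	0.014150597602908434	0.017742853831708604	0.8540012840218297
sample_003	north	fall	dcm	141.9368036556989	22.854550652205944	36.81684900261462	2.0678265898929804	0.13364581890100888	0.12930880334041928	2.030025946004238
sample_004	north	spring	dcm	131.53807930648327	26.67289321217686	38.23555778991431	2.9323224145243443	0.1447575529572223	0.2097184417019117	2.1242738810189
sample_005	north	fall	surface	49.971144646406174	26.8774145944044	39.21909698750824	1.1557299656780606	0.06526033276448574	0.07765751903775317	1.089878532203558
sample_006	north	spring	dcm	60.010966612026095	29.91226093750447	39.43742496240884	1.4549357741828488	0.07564254987626622	0.10620627900519033	1.7223707751513717
sample_007	north	fall	dcm	116.97332519106567	27.080165760591626	38.31004349607974	1.502611579262368	0.11065501198517051	0.1072237944316879	2.2882331915586147
sample_008	north	spring	dcm	66.69342867098749	25.85181335452944	39.63514286279678	1.2623586749213687	0.0790117461374499	0.07862753709023265	1.1429436271327302
sample_009	north	fall	dcm	124.4023927487433	24.37276879977435	39.21934214793146	2.034639169945107	0.13286163939450377	0.12265600231636646	1.8114977796466984
sample_010	north	spring	dcm	109.16571086272597	23.958041132427752	38.5748146045953	2.4207377109138584	0.11739571172903442	0.14078337302597374	1.579289539879423
sample_011	north	fall	dcm	175.95914602279663	28.27973290067166	39.26322301663458	3.9993173311531782	0.25151597141929044	0.25710684284616264	2.398491669364742
sample_012	north	spring	dcm	141.37494815513492	32.96174382418394	38.85310260113329	2.498535711263751	0.2092955276241484	0.1442890869153	2.758692600528677
sample_013	south	fall	dcm	146.3945189025253	24.48127262853086	39.75835867226124	2.81003516591259	0.1969625118621909	0.1679847328694088	2.041159051334468
sample_014	south	spring	dcm	186.3268855959177	31.771396193653345	39.740179783664644	2.806763461171219	0.19330327614814186	0.20107900690864242	2.4241238951543314
sample_015	south	fall	dcm	91.02411889471114	22.242006379179657	38.939743609167635	1.4860852262481357	0.07021573204369906	0.09761754953010293	1.0938024282167158
sample_016	south	spring	dcm	118.06394583545625	33.09765296149999	40.47363857366145	2.282481082102064	0.10406761160167237	0.13149777803136609	1.775808748265686
sample_017	south	fall	dcm	164.08721897751093	27.219540951773524	39.87296217121184	3.7399648205504996	0.18494433376776426	0.24009852155315006	2.7828246653620954
sample_018	south	spring	surface	44.823696091771126	27.30465621687472	39.36201361194253	0.7157728648332504	0.04245876108626578	0.04216343327809313	0.9087500779871264
sample_019	south	fall	dcm	82.33336587436497	31.128273463808	36.57632475439459	1.9708747282941952	0.09492369700652464	0.1524737821870032	1.3151293505994905
sample_020	south	spring	surface	7.722112163901329	25.995535604655743	37.72032100521028	0.16567833495121723	0.017542321098734246	0.011643339638848171	0.5618595673718194
sample_021	south	fall	dcm	140.14230906032026	26.732285821810365	40.03179193753749	2.9487853215455346	0.21745960005324533	0.1985887266333169	3.140913857538333
sample_022	south	spring	dcm	191.36749231256545	24.799531393684447	40.26538726501167	4.860365860643267	0.2515059412665795	0.296850724833331	2.254920506730355
sample_023	south	fall	surface	42.67040039412677	22.8592918952927	37.43767203949392	1.1424367728524394	0.04754984698723863	0.0720317668652811	0.8835637028821381
sample_024	south	spring	dcm	132.21230003982782	32.96060182899237	40.24666331335902	2.473281327755195	0.12755463607363	0.12425530131454608	2.260684164401678
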