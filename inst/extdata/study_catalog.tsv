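study_no	cross	n_qtls	population_type	population_size	traits
1	MoSQB-Low x MoSCSSS-Hight1	14	F2:3	282	RPR,EH
1	MoSCSSS-Hight2 x H25-LRP	16	F2:3	291	RPR,EH
1	Mo47 x MoSCSSS-Hight3	15	F2:3	291	RPR,EH
2	Mo17 x Huangzao4	6	RIL	239	PH,EH
3	NX531 x NX110	17	DH	162	PH,EH,IL,SD
4	EP42 x EP39	1	RIL	178	PH
5	SICAU1212 x B73	6	F2	233	SD,PH,EH
6	HZ32 x K12	4	F2	288	PH
7	H132 x S122	11	F2:3	217	PH,EH,IL
8	5003 x p138	5	RIL	450	PH,EH
9	A637 x A509	3	RIL	171	PH
10	HZ32 x K12	3	F2	247	PH
11	B73 x By804	3	RIL	200	RPR
11	H127R x Chang7-2	4	RIL	215	RPR
12	(Ye478 x Zheng58) x Ye478	8	DH	123	PH,EH
12	(Ye478 x Zheng58) x Zheng58	10	DH	163	PH,EH
13	Yu82 x Yu87-1	16	RIL	208	IL
13	Yu82 x Shen137	13	RIL	197	IL
13	Zong3 x Yu87-1	25	RIL	223	IL
13	Yu537A x Shen137	15	RIL	212	IL
14	PH6WC x PH4CV	8	DH	240	PH
15	L-20-01F x L-02-03D	8	F2:3	256	PH,EH
16	Z3 x 87-1	21	RIL	294	PH
16	Z3 x 87-1	25	IF2	441	PH
17	Zheng58 x W499	4	DH	118	EH
18	KUI3 x B77	29	RIL	177	PH,EH
19	Zheng58 x Chang7-2	9	F2:3	225	PH,EH
19	BT-1 x N6	12	RIL	250	PH,EH
20	37051 x LH277	1	F2	214	RPR
20	37051 x LH277	10	F2:3	214	RPR
21	Zong3 x 87-1	52	F2:3	266	PH
22	Zheng58 x Chang7-2	5	DH	190	RPR
23	teosinte x W22	3	BC6S6	259	PH,SD
24	Zheng58 x B73	11	F3:4	165	PH,EH
25	B52 x B73	34	RIL	200	DF,Lig
26	F286 x F838	15	RIL	242	Lig
27	B73 x Mo17	18	RIL	263	Lig,SSC
28	F288 x F271	21	RIL	131	Lig
29	Ce03005 x B73	14	F3,F4	211	DF
30	B73 x Ce03005	5	RIL	216	Cel,Lig,SBS
31	B73 x De811	44	RIL	191	DF,Lig
32	F271 x Cm484	28	RIL	267	Lig,SSC,Cel,Hem
33	B73 x Mo17	86	RIL	223	Lig,SSC
34	GY220 x 8984	19	F2:3	284	DF,Hem
34	GY220 x 8622	12	F2:3	265	DF,Hem
35	Zheng58 x HD568	11	RIL	220	DF,Cel,Lig
36	RIo x WM13	28	RIL	163	Cel,Hem,Lig
37	B73 x Mo17	56	DH	221	RPR,PD,SBS
38	Xu178 x K12	18	RIL	150	PH,EH
39	KA105 x KB020	21	F5	201	RPR,PH,EH
40	ROAM	25	RIL	1948	RPR
41	W22 x 8759	1	RIL	866	Vb
42	Y915 x Zheng58	13	RIL	171	SD,RPR
43	hengbai522 x tongxi5	4	RIL	198	RPR
44	X178 x NX531	23	RIL	248	Vb
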