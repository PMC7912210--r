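rank	symbol	raw_symbol
1	PRPH	PRPH
2	POU6F2	POU6F2
3	CNR2	CNR2
4	SALL4	SALL4
5	CNTD1	CNTD1
6	TPO	TPO
7	GLDC	GLDC
8	KLHDC9	KLHDC9
9	KCNA7	KCNA7
10	SYNJ2BP	SYNJ2BP
11	MMP20	MMP20
12	PRR7	PRR7
13	ROR2	ROR2
14	LRRC66	LRRC66
15	SYN3	SYN3
16	ULBP1	ULBP1
17	PLCZ1	PLCZ1
18	CATSPERB	CATSPERB
19	ZNF165	ZNF165
20	P2RX4	P2RX4
21	GIMAP7	GIMAP7
22	NKX3-2	NKX3.2
23	CSNK2A1	CSNK2A1
24	LIG1	LIG1
25	C10orf95	C10orf95
26	HOXD11	HOXD11
27	MRPL13	MRPL13
28	BRDT	BRDT
29	SYTL2	SYTL2
30	RBM20	RBM20
31	SPARCL1	SPARCL1
32	ZNF514	ZNF514
33	GRHL2	GRHL2
34	SLC18A1	SLC18A1
35	GNMT	GNMT
36	LRRC3B	LRRC3B
37	GZMA	GZMA
38	FAM118A	FAM118A
39	TDRD12	TDRD12
40	RPLP0	RPLP0
41	CXCL13	CXCL13
42	CCDC33	CCDC33
43	ZNF257	ZNF257
44	C1orf204	C1orf204
45	BOLA3	BOLA3
46	TSSK3	TSSK3
47	KANK3	KANK3
48	ENPP3	ENPP3
49	GSTA4	GSTA4
50	AKR1C3	AKR1C3
51	KLHDC4	KLHDC4
52	EXTL2	EXTL2
53	SIRT4	SIRT4
54	FGF9	FGF9
55	SCG5	SCG5
56	FUT8	FUT8
57	OOEP	OOEP
58	TNIP3	TNIP3
59	PDPR	PDPR
60	PLEKHA1	PLEKHA1
61	SOX7	SOX7
62	C16orf52	C16orf52
63	RASGEF1B	RASGEF1B
64	WDR63	WDR63
65	TBX21	TBX21
66	HLA-DQA2	HLA.DQA2
67	KLF2	KLF2
68	LTV1	LTV1
69	QRSL1	QRSL1
70	XCL1	XCL1
71	YLPM1	YLPM1
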