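rank	symbol	raw_symbol
1	PADI4	PADI4
2	CEACAM6	CEACAM6
3	SLC26A4	SLC26A4
4	MMP3	MMP3
5	LGSN	LGSN
6	C20orf85	C20orf85
7	DMRTC2	DMRTC2
8	EVPLL	EVPLL
9	TAS1R2	TAS1R2
10	HYAL3	HYAL3
11	TBCC	TBCC
12	VTCN1	VTCN1
13	SEPT4	X4.S EP
14	DISC1	DISC1
15	TDRD9	TDRD9
16	THBS2	THBS2
17	CHRM4	CHRM4
18	CCDC151	CCDC151
19	ALPP	ALPP
20	INSC	INSC
21	GPR45	GPR45
22	PCDHB5	PCDHB5
23	ITGA2B	ITGA2B
24	PLOD1	PLOD1
25	SLC30A3	SLC30A3
26	PRKAR2B	PRKAR2B
27	TMEM53	TMEM53
28	PCDHB12	PCDHB12
29	GUCY2D	GUCY2D
30	TCTE3	TCTE3
31	CEACAM4	CEACAM4
32	TNFSF13	TNFSF13
33	CNTNAP3	CNTNAP3
34	LRRC4C	LRRC4C
35	SEC14L4	SEC14L4
36	DHRS7C	DHRS7C
37	SLC26A9	SLC26A9
38	OLIG1	OLIG1
39	GRINA	GRINA
40	PVRL2	PVRL2
41	TENC1	TENC1
42	NEU4	NEU4
43	SIPA1L2	SIPA1L2
44	SPARC	SPARC
45	TREML1	TREML1
46	GBAP1	GBAP1
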