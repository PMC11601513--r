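# linker=ATATTGGACG
index	sequence
1	GGGGTGTG
2	CCTTTTTA
3	AGCGCCTG
4	TATCGCCG
5	TACTATCT
6	GCCCTACT
7	GAAAGATA
8	CTTTATAT
9	CTGCGCTT
10	CCTTAAAG
11	AGGCGGGC
12	CGAATCCC
13	ATACGCGA
14	CGTACCAC
15	TCGTTAGG
16	GCAGGGCT
17	GCCCCGCC
18	TAGATGGA
19	GTCTTTGA
20	TTTAGAGT
21	AGGCTTCA
22	ACCTCCAC
23	ACAGAAAC
24	CAATGGCA
25	CCTTCTGT
26	GGAGGCTG
27	GCGTCTTA
28	GCAGCATT
29	ACAGGAGA
30	TGTCACTG
31	CTACAGTT
32	CATAGTGT
33	CGAGGGAG
34	TACGGTAT
35	TACCACCA
36	ACGAAGAC
37	GTGGACCC
38	CTACACCA
39	AGGGATGC
40	TACGCGAG
41	CTGAACGC
42	GCAATCCA
43	GCACCAGC
44	AGCTACCG
45	GATAGGAG
46	AAGTGTAT
47	ACACTACG
48	GATCCTCT
49	CGCAGTAC
50	AGAATTTA
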