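# linker=ATCTACCTTG
index	sequence
1	TCCCAGAA
2	TGAAATTG
3	AGGTGAAC
4	TTTTCAGA
5	ACGATCTG
6	CCTGTGCC
7	GAAACTTT
8	CGTTTCTC
9	GGGAACTA
10	CCAACGTT
11	GCACATTT
12	ATTGGGGT
13	TAGGTCAT
14	ACTCAGCC
15	TTGGGGTT
16	CTTGAATT
17	ATATATCT
18	CATCGAGA
19	TCGACGGT
20	CGCGATTT
21	TTATTCTT
22	GCAACACT
23	CGCGCTCG
24	TCACGACA
25	TTCTTACA
26	GCGCTGCG
27	GTTGCCGT
28	CCCAGGAC
29	GCATTTAG
30	TGAGGCAT
31	GTGGTGGT
32	CATTGACC
33	CTGCAAAT
34	AGCCCTGC
35	AGCGGATT
36	CGTCGGTC
37	CTCGATGA
38	GGCTAATG
39	TCTCGTAG
40	GATGACAC
41	TCCAACAG
42	AGGGTTCA
43	AGTTTACT
44	TATAGGAC
45	ACTGTTTA
46	CCTTTGTA
47	CCTCTCAC
48	TGGCACAC
49	TTGGAAAA
50	AGTACGTC
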