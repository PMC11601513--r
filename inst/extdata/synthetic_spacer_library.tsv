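name	spacer	gene
GENE001_sg1	GCTGTTCCAATGGCTCCGAT	GENE001
GENE002_sg1	ATAAATCGTTCCCTAGCAGT	GENE002
GENE003_sg1	CAGAGGACTAACCCCGGTAT	GENE003
GENE004_sg1	CGTTAGAGATAACTACATAT	GENE004
GENE005_sg1	TATTGTGAAATGACCCAGAA	GENE005
GENE006_sg1	CAGCCCTACTCCCAATCGAC	GENE006
GENE007_sg1	AGGAGATTTTGATTGTAACA	GENE007
GENE008_sg1	CACAATCACGCGATCATAAT	GENE008
NTC_sg1	GCCGGAAATTTCTTGGTTCC	NA
NTC_sg2	AAATTTAACGCACGAACATT	NA
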