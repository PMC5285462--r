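FID	IID	CHR	BP1	BP2	TYPE	SCORE	SITES
S1	S1	chr1	100001	200000	1	0	15
S1	S1	chr1	300001	400000	3	0	14
S2	S2	chr1	500001	599999	1	0	50
S2	S2	chr2	1	1000000	3	0	14
S3	S3	chr2	100001	199999	1	0	15
S3	S3	chr2	2000001	2250000	3	0	40
S4	S4	chr3	1	500000	1	0	100
S4	S4	chr3	600000	700000	3	0	16
S5	S5	chr1	700001	850000	1	0	15
S5	S5	chr2	3000001	3100000	3	0	200
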