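true_site	ISFR	GGNP	AKZN	CRNP	MSSE	MTCM	MANB	DEFR	CMNP	DJBR	unknown_queries
ISFR	3	0	0	0	1	0	0	0	0	0	0
GGNP	0	6	1	0	1	2	0	0	0	0	9
AKZN	0	1	4	2	3	1	0	0	0	0	1
CRNP	0	0	1	5	0	1	0	0	0	1	1
MSSE	0	1	1	0	5	1	0	0	0	0	6
MTCM	0	0	1	0	0	10	0	0	0	0	15
MANB	0	0	0	0	0	1	4	4	1	0	3
DEFR	0	0	0	1	0	0	2	4	0	1	0
CMNP	0	0	0	0	0	0	0	0	5	3	4
DJBR	0	1	0	0	0	0	0	3	2	4	7
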