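allele	MPP	TEA	ASP	morphine	metformin	tropisetron	O_desmethyltramadol	debrisoquine	tyramine	monocrotaline
*1	100	100	100	100	100	100	100	100	100	100
*2	95	40	92	20	25	5	0	60	15	10
*3	25	20	18	12	15	10	12	28	10	15
*4	5	3	10	0	2	8	4	28	3	6
*5	2	0	1	0	2	0	0	3	1	0
*6	1	2	0	0	1	0	0	2	0	1
*7	93	60	96	35	10	20	15	70	0	25
*8	110	165	105	170	160	100	120	95	105	175
*9	100	105	98	168	110	95	100	97	102	96
*10	91	30	94	25	8	0	12	55	18	20
*11	96	45	92	15	20	12	0	65	22	18
*12	2	1	0	0	1	2	0	3	1	0
*13	92	30	85	28	15	25	30	88	25	30
*14	15	10	12	5	8	6	5	25	7	10
*15	0	2	1	0	0	1	0	2	0	1
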