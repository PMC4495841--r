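population	*1	*2	*3	*4	*5	*6	*7	*8	*9	*10	*11	*12	*13	*14	*15	*16
San	11	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0
Mbuti Pygmy	20	2	0	0	0	0	0	4	0	0	0	0	0	0	0	0
Biaka Pygmy	40	6	0	0	0	0	5	1	0	0	0	0	0	0	0	0
Bantu S.W.	14	1	0	0	0	0	1	0	0	0	0	0	0	0	0	0
Bantu N.E.	14	2	0	0	0	0	2	4	0	0	0	0	0	0	0	0
Bantu (LWK-1K)	171	8	0	0	0	0	5	10	0	0	0	0	0	0	0	0
Mandenka	40	2	0	0	0	0	1	1	0	0	0	0	0	0	0	0
Yoruba	42	0	0	0	0	0	1	1	0	0	0	0	0	0	0	0
Yoruba (YRI-1K)	159	4	0	0	0	0	3	10	0	0	0	0	0	0	0	0
Mozabite	48	7	0	1	0	1	1	0	0	0	0	0	0	0	0	0
Bedouin	67	9	10	0	3	0	2	1	0	0	0	0	0	0	0	0
Palestinian	71	12	3	0	0	2	2	0	0	0	0	0	0	0	0	0
Druze	65	15	4	0	0	0	0	0	0	0	0	0	0	0	0	0
Tuscan	14	2	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Tuscan (TSI-1K)	140	37	11	5	1	0	0	1	1	0	0	0	0	0	0	0
Sardinian	39	12	1	3	0	1	0	0	0	0	0	0	0	0	0	0
North Italian	25	2	1	0	0	0	0	0	0	0	0	0	0	0	0	0
Iberian (IBS-1K)	21	4	1	2	0	0	0	0	0	0	0	0	0	0	0	0
French Basque	35	9	2	2	0	0	0	0	0	0	0	0	0	0	0	0
French	35	12	4	1	3	1	0	0	0	0	0	0	0	0	0	0
British (GBR-1K)	129	29	9	4	6	1	0	0	0	0	0	0	0	0	0	0
Orcadian	24	4	2	0	0	0	0	0	0	0	0	0	0	0	0	0
German	167	37	19	5	6	0	0	0	0	0	0	0	0	0	0	0
Finn (FIN-1K)	146	25	10	3	2	0	0	0	0	0	0	0	0	0	0	0
Adygei	24	6	2	0	1	0	0	0	1	0	0	0	0	0	0	0
Russian	33	5	5	3	4	0	0	0	0	0	0	0	0	0	0	0
Balochi	32	13	2	0	0	0	0	1	0	0	0	0	0	0	0	0
Brahui	31	12	3	0	3	0	0	0	0	0	0	0	1	0	0	0
Makrani	42	8	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Sindhi	40	6	0	0	0	0	2	0	0	0	0	0	0	0	0	0
Pathan	36	13	1	0	0	0	0	0	0	0	0	0	0	0	0	0
Kalash	34	8	3	0	0	0	0	0	0	0	0	0	1	0	0	0
Burusho	42	3	3	0	2	0	0	0	0	0	0	0	0	0	0	0
Hazara	41	2	1	0	0	1	0	0	0	0	0	0	0	1	0	0
Uygur	16	3	1	0	0	0	0	0	0	0	0	0	0	0	0	0
Yakut	46	0	2	0	0	0	0	0	2	0	0	0	0	0	0	0
Dai	20	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
She	18	0	0	0	0	0	0	0	0	0	0	2	0	0	0	0
Tujia	20	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Yizu	20	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Naxi	17	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0
Tu	18	0	0	0	0	0	0	0	0	0	0	0	0	1	1	0
Xibo	18	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Mongola	17	2	0	0	0	0	0	0	1	0	0	0	0	0	0	0
Hezhen	18	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Daur	20	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Oroqen	18	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Han	90	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Han Beijing (CHB-1K)	191	1	0	0	0	0	0	0	1	0	1	0	0	0	0	0
Han South (CHS-1K)	200	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Lahu	16	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Miaozu	20	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Cambodian	19	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Japanese	60	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Japanese (JPT-1K)	178	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Melanesian	28	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Papuan	34	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Colombian	8	6	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Karitiana	11	17	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Maya	28	14	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Pima	23	5	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Surui	1	15	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Colombian (CLM-1K)	79	35	4	1	1	0	0	0	0	0	0	0	0	0	0	0
Mexican (MXL-1K)	78	43	6	0	4	0	1	0	0	0	0	0	0	0	0	0
Puerto Rican (PUR-1K)	84	22	1	0	2	0	0	0	1	0	0	0	0	0	0	0
Caucasians (CEU-1K)	123	26	15	3	2	1	0	0	0	0	0	0	0	0	0	0
Africans (ASW-1K)	107	10	0	2	1	0	0	1	0	0	0	0	0	0	1	0
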