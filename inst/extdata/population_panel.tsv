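population	region	n_individuals	n_chromosomes	admixed	source
San	Sub-Saharan Africa	6	12	FALSE	HGDP
Mbuti Pygmy	Sub-Saharan Africa	13	26	FALSE	HGDP
Biaka Pygmy	Sub-Saharan Africa	26	52	FALSE	HGDP
Bantu S.W.	Sub-Saharan Africa	8	16	FALSE	HGDP
Bantu N.E.	Sub-Saharan Africa	11	22	FALSE	HGDP
Bantu (LWK-1K)	Sub-Saharan Africa	97	194	FALSE	1KG
Mandenka	Sub-Saharan Africa	22	44	FALSE	HGDP
Yoruba	Sub-Saharan Africa	22	44	FALSE	HGDP
Yoruba (YRI-1K)	Sub-Saharan Africa	88	176	FALSE	1KG
Mozabite	North Africa and Middle East	29	58	FALSE	HGDP
Bedouin	North Africa and Middle East	46	92	FALSE	HGDP
Palestinian	North Africa and Middle East	45	90	FALSE	HGDP
Druze	North Africa and Middle East	42	84	FALSE	HGDP
Tuscan	Europe	8	16	FALSE	HGDP
Tuscan (TSI-1K)	Europe	98	196	FALSE	1KG
Sardinian	Europe	28	56	FALSE	HGDP
North Italian	Europe	14	28	FALSE	HGDP
Iberian (IBS-1K)	Europe	14	28	FALSE	1KG
French Basque	Europe	24	48	FALSE	HGDP
French	Europe	28	56	FALSE	HGDP
British (GBR-1K)	Europe	89	178	FALSE	1KG
Orcadian	Europe	15	30	FALSE	HGDP
German	Europe	117	234	FALSE	HGDP
Finn (FIN-1K)	Europe	93	186	FALSE	1KG
Adygei	Europe	17	34	FALSE	HGDP
Russian	Europe	25	50	FALSE	HGDP
Balochi	Central Asia	24	48	FALSE	HGDP
Brahui	Central Asia	25	50	FALSE	HGDP
Makrani	Central Asia	25	50	FALSE	HGDP
Sindhi	Central Asia	24	48	FALSE	HGDP
Pathan	Central Asia	25	50	FALSE	HGDP
Kalash	Central Asia	23	46	FALSE	HGDP
Burusho	Central Asia	25	50	FALSE	HGDP
Hazara	Central Asia	23	46	FALSE	HGDP
Uygur	Central Asia	10	20	FALSE	HGDP
Yakut	Central Asia	25	50	FALSE	HGDP
Dai	East Asia and Oceania	10	20	FALSE	HGDP
She	East Asia and Oceania	10	20	FALSE	HGDP
Tujia	East Asia and Oceania	10	20	FALSE	HGDP
Yizu	East Asia and Oceania	10	20	FALSE	HGDP
Naxi	East Asia and Oceania	9	18	FALSE	HGDP
Tu	East Asia and Oceania	10	20	FALSE	HGDP
Xibo	East Asia and Oceania	9	18	FALSE	HGDP
Mongola	East Asia and Oceania	10	20	FALSE	HGDP
Hezhen	East Asia and Oceania	9	18	FALSE	HGDP
Daur	East Asia and Oceania	10	20	FALSE	HGDP
Oroqen	East Asia and Oceania	9	18	FALSE	HGDP
Han	East Asia and Oceania	45	90	FALSE	HGDP
Han Beijing (CHB-1K)	East Asia and Oceania	97	194	FALSE	1KG
Han South (CHS-1K)	East Asia and Oceania	100	200	FALSE	1KG
Lahu	East Asia and Oceania	8	16	FALSE	HGDP
Miaozu	East Asia and Oceania	10	20	FALSE	HGDP
Cambodian	East Asia and Oceania	10	20	FALSE	HGDP
Japanese	East Asia and Oceania	30	60	FALSE	HGDP
Japanese (JPT-1K)	East Asia and Oceania	89	178	FALSE	1KG
Melanesian	East Asia and Oceania	14	28	FALSE	HGDP
Papuan	East Asia and Oceania	17	34	FALSE	HGDP
Colombian	America	7	14	FALSE	HGDP
Karitiana	America	14	28	FALSE	HGDP
Maya	America	21	42	FALSE	HGDP
Pima	America	14	28	FALSE	HGDP
Surui	America	8	16	FALSE	HGDP
Colombian (CLM-1K)	Admixed	60	120	TRUE	1KG
Mexican (MXL-1K)	Admixed	66	132	TRUE	1KG
Puerto Rican (PUR-1K)	Admixed	55	110	TRUE	1KG
Caucasians (CEU-1K)	Admixed	85	170	TRUE	1KG
Africans (ASW-1K)	Admixed	61	122	TRUE	1KG
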