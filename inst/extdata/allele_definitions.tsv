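allele	variants	parent	category
*1		NA	reference
*2	Met420del	NA	major
*3	Arg61Cys	NA	major
*4	Gly401Ser	NA	major
*5	Gly465Arg,Met420del	NA	major
*6	Cys88Arg,Met420del	NA	major
*7	Ser14Phe	NA	major
*8	Arg488Met	NA	major
*9	Pro117Leu	NA	major
*10	Ser189Leu	NA	major
*11	Ile449Thr	NA	major
*12	Ser29Leu	NA	major
*13	Thr245Met	NA	major
*14	Arg206Cys,Met420del	NA	major
*15	Glu284Lys	NA	major
*16	NA	NA	unknown
*1B	Met408Val	*1	sub
*1C	Pro341Leu	*1	sub
*1D	Phe160Leu	*1	sub
*1E	Arg342His	*1	sub
*1F	Gly414Ala	*1	sub
*1G	Met408Val,Pro341Leu	*1	sub
*2B	Met420del,Met408Val	*2	sub
*3B	Arg61Cys,Met408Val	*3	sub
*4B	Gly401Ser,Met408Val	*4	sub
*5B	Gly465Arg,Met420del,Met408Val	*5	sub
*7A	Ser14Phe,Arg342His	*7	sub
*7B	Ser14Phe,Met408Val	*7	sub
*8B	Arg488Met,Arg342His	*8	sub
*13B	Thr245Met,Met408Val	*13	sub
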