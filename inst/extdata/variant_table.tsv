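variant_id	codon	ref_residue	alt_residue	rs_id	functional_override
Ser14Phe	14	S	F	rs34447885	NA
Ser29Leu	29	S	L	NA	NA
Arg61Cys	61	R	C	rs12208357	NA
Cys88Arg	88	C	R	rs55918055	LOF
Gln97Lys	97	Q	K	NA	NA
Pro117Leu	117	P	L	NA	NA
Phe160Leu	160	F	L	rs683369	non_LOF
Ser189Leu	189	S	L	NA	NA
Arg206Cys	206	R	C	NA	LOF
Gly220Val	220	G	V	NA	NA
Thr245Met	245	T	M	NA	NA
Glu284Lys	284	E	K	NA	NA
Pro341Leu	341	P	L	rs2282143	non_LOF
Arg342His	342	R	H	NA	non_LOF
Gly401Ser	401	G	S	rs34130495	NA
Met408Val	408	M	V	rs628031	non_LOF
Gly414Ala	414	G	A	NA	non_LOF
Met420del	420	M	del	rs72552763	NA
Ile449Thr	449	I	T	NA	NA
Gly465Arg	465	G	R	rs34059508	LOF
Arg488Met	488	R	M	NA	NA
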