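marker_id	gene	codon	ref_aa	mut_aa	alias	variant_class	association	genomic_contig	genomic_pos	inserted_seq
vgsc_L1014F	vgsc	1014	Leu	Phe	L1014F (kdr)	missense	pyrethroid/DDT (kdr)	NA	NA	NA
vgsc_L1014S	vgsc	1014	Leu	Ser	L1014S (kdr)	missense	pyrethroid/DDT (kdr)	NA	NA	NA
vgsc_V410L	vgsc	410	Val	Leu	V410L	missense	pyrethroid	NA	NA	NA
vgsc_F1508C	vgsc	1508	Phe	Cys	F1508C	missense	pyrethroid	NA	NA	NA
vgsc_N1549Y	vgsc	1549	Asn	Tyr	N1549Y	missense	pyrethroid	NA	NA	NA
vgsc_D1763Y	vgsc	1763	Asp	Tyr	D1763Y	missense	pyrethroid	NA	NA	NA
ace1_G119S	ace-1	119	Gly	Ser	G119S	missense	organophosphate/carbamate	NA	NA	NA
ace1_N643I	ace-1	643	Asn	Ile	N485I (Torpedo californica)	missense	carbamate (bendiocarb)	NA	NA	NA
rdl_A296S	rdl	296	Ala	Ser	A296S (rdl)	missense	cyclodiene (dieldrin)	NA	NA	NA
gste2_L119F	GSTe2	119	Leu	Phe	L119F	missense	DDT	NA	NA	NA
cyp6p9a_ins	CYP6P9a	NA	NA	NA	CYP6P9a promoter 2-bp insertion	promoter_indel	pyrethroid	2RL	8570149	AT
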