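## lemna-core configuration B (INS); 68 reactions
# name lemna_core_B_INS
# metabolite Glc_x x 6 external
# metabolite Gln_x x 5 external
# metabolite CO2atm_x x 1 external
# metabolite CO2out_x x 1 external
# metabolite G6P_c c 6 balanced
# metabolite F6P_c c 6 balanced
# metabolite TP_c c 3 balanced
# metabolite PGA_c c 3 balanced
# metabolite PEP_c c 3 balanced
# metabolite Pyr_c c 3 balanced
# metabolite P5P_c c 5 balanced
# metabolite E4P_c c 4 balanced
# metabolite S7P_c c 7 balanced
# metabolite G6P_p p 6 balanced
# metabolite F6P_p p 6 balanced
# metabolite TP_p p 3 balanced
# metabolite PGA_p p 3 balanced
# metabolite PEP_p p 3 balanced
# metabolite Pyr_p p 3 balanced
# metabolite P5P_p p 5 balanced
# metabolite E4P_p p 4 balanced
# metabolite S7P_p p 7 balanced
# metabolite RuBP_p p 5 balanced
# metabolite PG2_p p 2 balanced
# metabolite AcCoA_p p 2 balanced
# metabolite Pyr_m m 3 balanced
# metabolite AcCoA_m m 2 balanced
# metabolite Cit_m m 6 balanced
# metabolite KG_m m 5 balanced
# metabolite Suc_m m 4 balanced
# metabolite OAAx merged 4 balanced
# metabolite CO2 merged 1 balanced
# metabolite Gln_c c 5 balanced
# metabolite Glu_c c 5 balanced
# metabolite Val_c c 5 balanced
# metabolite Ile_c c 6 balanced
# metabolite Phe_c c 9 balanced
# metabolite CO2_RBC p 1 balanced
# metabolite Ala_bm x 3 external
# metabolite Glu_bm x 5 external
# metabolite Gln_bm x 5 external
# metabolite Ser_bm x 3 external
# metabolite Gly_bm x 2 external
# metabolite C1_bm x 1 external
# metabolite His_bm x 5 external
# metabolite Phe_bm x 9 external
# metabolite Tyr_bm x 9 external
# metabolite Val_bm x 5 external
# metabolite Leu_bm x 6 external
# metabolite Ile_bm x 6 external
# metabolite Thr_bm x 4 external
# metabolite Asx_bm x 4 external
# metabolite Lys_bm x 6 external
# metabolite Glyc_bm x 3 external
# metabolite FA_bm x 2 external
# metabolite GlcF_bm x 6 external
# metabolite Cit_bm x 6 external
# metabolite Mal_bm x 4 external
# metabolite Fruc_bm x 6 external
# metabolite St_bm x 6 external
# metabolite CW_bm x 6 external
# fixed vGln_up 0
# ratio vRBC vRBO 1000
# ratio vFUM1 vFUM2 1
vGlc_up	Glc_x#abcdef	G6P_c#abcdef	irr	0	2000
vGln_up	Gln_x#abcde	Gln_c#abcde	irr	0	2000
vPGI_c	G6P_c#abcdef	F6P_c#abcdef	rev	-2000	2000
vALD_c	F6P_c#abcdef	TP_c#cba + TP_c#def	rev	-2000	2000
vGAPDH_c	TP_c#abc	PGA_c#abc	rev	-2000	2000
vENO_c	PGA_c#abc	PEP_c#abc	rev	-2000	2000
vPK_c	PEP_c#abc	Pyr_c#abc	irr	0	2000
vPGI_p	G6P_p#abcdef	F6P_p#abcdef	rev	-2000	2000
vALD_p	F6P_p#abcdef	TP_p#cba + TP_p#def	rev	-2000	2000
vGAPDH_p	TP_p#abc	PGA_p#abc	rev	-2000	2000
vENO_p	PGA_p#abc	PEP_p#abc	rev	-2000	2000
vPK_p	PEP_p#abc	Pyr_p#abc	irr	0	2000
vG6PDH_c	G6P_c#abcdef	P5P_c#bcdef + CO2#a	irr	0	2000
vG6PDH_p	G6P_p#abcdef	P5P_p#bcdef + CO2#a	irr	0	2000
vTK1_c	P5P_c#abcde + P5P_c#fghij	S7P_c#abfghij + TP_c#cde	rev	-2000	2000
vTA_c	S7P_c#abcdefg + TP_c#hij	E4P_c#defg + F6P_c#abchij	rev	-2000	2000
vTK2_c	P5P_c#abcde + E4P_c#fghi	F6P_c#abfghi + TP_c#cde	rev	-2000	2000
vTK1_p	P5P_p#abcde + P5P_p#fghij	S7P_p#abfghij + TP_p#cde	rev	-2000	2000
vTA_p	S7P_p#abcdefg + TP_p#hij	E4P_p#defg + F6P_p#abchij	rev	-2000	2000
vTK2_p	P5P_p#abcde + E4P_p#fghi	F6P_p#abfghi + TP_p#cde	rev	-2000	2000
vG6Pt	G6P_c#abcdef	G6P_p#abcdef	rev	-2000	2000
vTPt	TP_c#abc	TP_p#abc	rev	-2000	2000
vPEPt	PEP_c#abc	PEP_p#abc	rev	-2000	2000
vPGAt	PGA_c#abc	PGA_p#abc	rev	-2000	2000
vPRK	P5P_p#abcde	RuBP_p#abcde	irr	0	2000
vRBC	RuBP_p#abcde + CO2_RBC#f	PGA_p#cde + PGA_p#fba	irr	0	2000
vRBO	RuBP_p#abcde	PGA_p#cde + PG2_p#ba	irr	0	10
vPR	PG2_p#ab + PG2_p#cd	PGA_p#abd + CO2#c	irr	0	10
vPyrT_cm	Pyr_c#abc	Pyr_m#abc	irr	0	2000
vPDH_m	Pyr_m#abc	AcCoA_m#bc + CO2#a	irr	0	2000
vPDH_p	Pyr_p#abc	AcCoA_p#bc + CO2#a	irr	0	2000
vCS	OAAx#abcd + AcCoA_m#ef	Cit_m#dcbfea	irr	0	2000
vIDH	Cit_m#abcdef	KG_m#abcde + CO2#f	irr	0	2000
vKGDH	KG_m#abcde	Suc_m#bcde + CO2#a	irr	0	2000
vFUM1	Suc_m#abcd	OAAx#abcd	irr	0	2000
vFUM2	Suc_m#abcd	OAAx#dcba	irr	0	2000
vPEPC	PEP_c#abc + CO2#d	OAAx#abcd	rev	-2000	2000
vGlnGlu	Gln_c#abcde	Glu_c#abcde	rev	-2000	2000
vGluKG	Glu_c#abcde	KG_m#abcde	rev	-2000	2000
vCO2_out	CO2#a	CO2out_x#a	irr	0	2000
vCO2_up	CO2atm_x#a	CO2_RBC#a	irr	0	2000
vCO2_rel	CO2_RBC#a	CO2out_x#a	irr	0	2000
vCO2X	CO2#a	CO2_RBC#a	rev	-2000	2000
vValS	Pyr_p#abc + Pyr_p#def	Val_c#abecf + CO2#d	irr	0	2000
vIleS	OAAx#abcd + Pyr_c#efg	Ile_c#abfcdg + CO2#e	irr	0	2000
vPheS	PEP_c#abc + PEP_c#def + E4P_c#ghij	Phe_c#defbcghij + CO2#a	irr	0	2000
vAlaP	Pyr_c#abc	Ala_bm#abc	irr	0	2000
vGluP	Glu_c#abcde	Glu_bm#abcde	irr	0	2000
vGlnP	Gln_c#abcde	Gln_bm#abcde	irr	0	2000
vSerP	PGA_c#abc	Ser_bm#abc	irr	0	2000
vGlyP	PGA_c#abc	Gly_bm#ab + C1_bm#c	irr	0	2000
vHisP	P5P_c#abcde	His_bm#abcde	irr	0	2000
vPheP	Phe_c#abcdefghi	Phe_bm#abcdefghi	irr	0	2000
vTyrP	PEP_c#abc + PEP_c#def + E4P_c#ghij	Tyr_bm#defbcghij + CO2#a	irr	0	2000
vValP	Val_c#abcde	Val_bm#abcde	irr	0	2000
vLeuP	Pyr_p#abc + Pyr_p#def + AcCoA_p#gh	Leu_bm#ghbecf + CO2#a + CO2#d	irr	0	2000
vIleP	Ile_c#abcdef	Ile_bm#abcdef	irr	0	2000
vThrP	OAAx#abcd	Thr_bm#abcd	irr	0	2000
vAsxP	OAAx#abcd	Asx_bm#abcd	irr	0	2000
vLysP	OAAx#abcd + Pyr_c#efg	Lys_bm#abcdfg + CO2#e	irr	0	2000
vGlyc_out	TP_c#abc	Glyc_bm#abc	irr	0	2000
vFASp	AcCoA_p#ab	FA_bm#ab	irr	0	2000
vGlc_out	G6P_c#abcdef	GlcF_bm#abcdef	irr	0	2000
vCit_out	Cit_m#abcdef	Cit_bm#abcdef	irr	0	2000
vMal_out	OAAx#abcd	Mal_bm#abcd	irr	0	2000
vFruc_out	F6P_c#abcdef	Fruc_bm#abcdef	irr	0	2000
vSt_out	G6P_p#abcdef	St_bm#abcdef	irr	0	2000
vHPc_out	G6P_c#abcdef	CW_bm#abcdef	irr	0	2000
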