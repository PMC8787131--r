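mirna_id	mirna_name	mirna_fc	mirna_fdr	mirna_regulation	mirna_raw_p_lt_0.05	target_seqname	target_symbol	target_fdr	target_fc_abs	target_regulation
147186	mmu-miR-200b-3p	0.658254	0.041228	Down	FALSE	ENSMUST00000159119	Gas5	0.04911062	2.3057933	Down
42883	mmu-miR-883b-3p	0.56954	0.039109	Down	FALSE	ENSMUST00000148977	4930417H01Rik	0.04292526	1.6698261	Up
42883	mmu-miR-883b-3p	0.56954	0.039109	Down	FALSE	ENSMUST00000160227	AI480526	0.03374033	1.9144645	Up
11091	mmu-miR-377-3p	0.471786	0.066332	Down	TRUE	ENSMUST00000126472	5930412G12Rik	0.03637584	1.8078425	Up
11091	mmu-miR-377-3p	0.471786	0.066332	Down	TRUE	ENSMUST00000165938	6430628N08Rik	0.04965351	1.5305915	Up
11091	mmu-miR-377-3p	0.471786	0.066332	Down	TRUE	NR_015500	A530013C23Rik	0.04294613	2.0565884	Up
11091	mmu-miR-377-3p	0.471786	0.066332	Down	TRUE	ENSMUST00000155013	A930007I19Rik	0.04227756	1.5199345	Up
11091	mmu-miR-377-3p	0.471786	0.066332	Down	TRUE	ENSMUST00000132811	Gm15489	0.04533299	2.6704226	Up
11091	mmu-miR-377-3p	0.471786	0.066332	Down	TRUE	ENSMUST00000162649	Gm16251	0.04966378	1.9383893	Up
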