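subject_id	vhl_hgvs_c	vhl_classification	zygosity	deleted_exons	differential_findings	evaluated_in_genetics	age_years	sex	personal_tumors	personal_features	non_vhl_tumors	family_history_vhl	family_degree	somatic_tested	somatic_alterations
MD01	c.341-1G>A	P	heterozygous		none	true	34	female	cns_hemangioblastoma:1;retinal_hemangioblastoma:1	multiple_pancreatic_cysts		positive	first	false	
MD02	c.208G>A	VUS	heterozygous		none	true	16	female				positive	first	false	
MD03	c.340+578C>T	VUS	heterozygous		none	true	66	male			prostate cancer	negative		false	
MD04	c.25G>A	B	heterozygous		none	true	59	female				negative		false	
MD05	c.345C>A	VUS	heterozygous		none	true	44	female	cns_hemangioblastoma:1			negative		false	
MD06	c.292T>C	P	heterozygous		SDHB:P	true	51	male	pheochromocytoma:1			negative		false	
MD07	c.464-1G>C	P	heterozygous		none	true	39	female	rcc:2			negative		true	c.506_509delinsCG|snv|32||180|25|0||rcc;|one_copy_deletion||-0.85|||||rcc
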