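subject_id	vhl_hgvs_c	vhl_classification	zygosity	deleted_exons	differential_findings	evaluated_in_genetics	age_years	sex	personal_tumors	personal_features	non_vhl_tumors	family_history_vhl	family_degree	somatic_tested	somatic_alterations
P21	c.208G>A	VUS	heterozygous		none	true	16	female				positive	first	false	
P22	c.345C>A	VUS	heterozygous		none	true		female	cns_hemangioblastoma:1			negative		false	
P23	c.532C>G	VUS	heterozygous		none	true		male	paraganglioma:1			negative		false	
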