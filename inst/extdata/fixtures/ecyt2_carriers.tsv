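subject_id	vhl_hgvs_c	vhl_classification	zygosity	deleted_exons	differential_findings	evaluated_in_genetics	age_years	sex	personal_tumors	personal_features	non_vhl_tumors	family_history_vhl	family_degree	somatic_tested	somatic_alterations
EC01	c.598C>T	P_ECYT2	heterozygous		none	true	41	female				negative		false	
EC02	c.598C>T	P_ECYT2	heterozygous		none	true	55	male				negative		false	
EC03	c.388G>A	P_ECYT2	heterozygous		none	true	38	female				negative		false	
EC04	c.562C>G	P_ECYT2	heterozygous		none	true	47	male				negative		false	
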