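subject_id	vhl_hgvs_c	vhl_classification	zygosity	deleted_exons	differential_findings	evaluated_in_genetics	age_years	sex	personal_tumors	personal_features	non_vhl_tumors	family_history_vhl	family_degree	somatic_tested	somatic_alterations
PV01	c.340+578C>T	VUS	heterozygous		none	true	45	female				negative		false	
PV02	c.340+578C>T	VUS	heterozygous		none	true	52	male				negative		false	
PV03	c.340+578C>T	VUS	heterozygous		none	true	61	female				negative		false	
PV04	c.340+578C>T	VUS	heterozygous		none	true	58	female				negative		false	
PV05	c.340+578C>T	VUS	heterozygous		none	true	66	male			breast cancer	negative		false	
PV06	c.340+578C>T	VUS	heterozygous		none	true	49	female			colon cancer	negative		false	
PV07	c.340+578C>T	VUS	heterozygous		none	true	71	female			melanoma	negative		false	
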