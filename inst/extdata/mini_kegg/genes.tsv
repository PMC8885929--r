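# gmlink-kegg-snapshot v1 cel
cel:CELE_bcat-1	bcat-1
cel:CELE_bcat-1	BCAT1
cel:CELE_bcat-1	K02A4.1
cel:CELE_bckd-1A	bckd-1A
cel:CELE_bckd-1A	BCKDHA
cel:CELE_bckd-1B	bckd-1B
cel:CELE_bckd-1B	BCKDHB
cel:CELE_dbt-1	dbt-1
cel:CELE_dbt-1	DBT
cel:CELE_ech-6	ech-6
cel:CELE_ech-6	ECHS1
cel:CELE_acdh-1	acdh-1
cel:CELE_acdh-1	ACADSB
cel:CELE_hach-1	hach-1
cel:CELE_hach-1	HIBCH
cel:CELE_mce-1	mce-1
cel:CELE_mce-1	MCEE
cel:CELE_pcca-1	pcca-1
cel:CELE_pcca-1	PCCA
cel:CELE_pccb-1	pccb-1
cel:CELE_pccb-1	PCCB
cel:CELE_cts-1	cts-1
cel:CELE_cts-1	CS
cel:CELE_aco-2	aco-2
cel:CELE_aco-2	ACO2
cel:CELE_idh-1	idh-1
cel:CELE_idh-1	IDH1
cel:CELE_ogdh-1	ogdh-1
cel:CELE_ogdh-1	OGDH
cel:CELE_suca-1	suca-1
cel:CELE_suca-1	SUCLA
cel:CELE_sdha-1	sdha-1
cel:CELE_sdha-1	SDHA
cel:CELE_fum-1	fum-1
cel:CELE_fum-1	FH
cel:CELE_mdh-1	mdh-1
cel:CELE_mdh-1	MDH1
cel:CELE_nuo-1	nuo-1
cel:CELE_nuo-1	NDUFV1
cel:CELE_nuo-2	nuo-2
cel:CELE_nuo-2	NDUFS3
cel:CELE_cyc-1	cyc-1
cel:CELE_cyc-1	CYC1
cel:CELE_cco-1	cco-1
cel:CELE_cco-1	COX5B
cel:CELE_atp-2	atp-2
cel:CELE_atp-2	ATP5B
cel:CELE_atp-3	atp-3
cel:CELE_atp-3	ATP5O
cel:CELE_gta-1	gta-1
cel:CELE_gta-1	GABAT
cel:CELE_alh-7	alh-7
cel:CELE_alh-7	ALDH7A1
cel:CELE_pyd-1	pyd-1
cel:CELE_pyd-1	DPYD
cel:CELE_sptl-1	sptl-1
cel:CELE_sptl-1	SPTLC1
cel:CELE_cerk-1	cerk-1
cel:CELE_cerk-1	CERK
cel:CELE_asah-1	asah-1
cel:CELE_asah-1	ASAH1
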