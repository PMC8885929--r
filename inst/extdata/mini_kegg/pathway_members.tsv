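# gmlink-kegg-snapshot v1 cel
cel00280	cel:CELE_bcat-1
cel00280	cel:CELE_bckd-1A
cel00280	cel:CELE_bckd-1B
cel00280	cel:CELE_dbt-1
cel00280	cel:CELE_ech-6
cel00280	cel:CELE_acdh-1
cel00280	cel:CELE_hach-1
cel00280	cel:CELE_mce-1
cel00280	cel:CELE_pcca-1
cel00280	cel:CELE_pccb-1
cel00280	C00183
cel00280	C00123
cel00280	C00407
cel00280	C00091
cel00280	C00024
cel00020	cel:CELE_cts-1
cel00020	cel:CELE_aco-2
cel00020	cel:CELE_idh-1
cel00020	cel:CELE_ogdh-1
cel00020	cel:CELE_suca-1
cel00020	cel:CELE_sdha-1
cel00020	cel:CELE_fum-1
cel00020	cel:CELE_mdh-1
cel00020	C00149
cel00020	C00042
cel00020	C00122
cel00020	C00036
cel00020	C00158
cel00020	C00091
cel00020	C00022
cel00020	C00024
cel00020	C00068
cel00190	cel:CELE_nuo-1
cel00190	cel:CELE_nuo-2
cel00190	cel:CELE_cyc-1
cel00190	cel:CELE_cco-1
cel00190	cel:CELE_atp-2
cel00190	cel:CELE_atp-3
cel00410	cel:CELE_gta-1
cel00410	cel:CELE_alh-7
cel00410	cel:CELE_pyd-1
cel00410	C00099
cel00410	C00041
cel00410	C00049
cel00410	C00022
cel00600	cel:CELE_sptl-1
cel00600	cel:CELE_cerk-1
cel00600	cel:CELE_asah-1
cel00600	C00550
cel00600	C00346
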