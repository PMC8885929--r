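# gmlink-kegg-snapshot v1 cel
cel00280	Valine, leucine and isoleucine degradation
cel00020	Citrate cycle (TCA cycle)
cel00190	Oxidative phosphorylation
cel00410	beta-Alanine metabolism
cel00600	Sphingolipid metabolism
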