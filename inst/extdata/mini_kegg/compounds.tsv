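# gmlink-kegg-snapshot v1 cel
C00183	L-Valine
C00183	Valine
C00183	2-Amino-3-methylbutyric acid
C00123	L-Leucine
C00123	Leucine
C00407	L-Isoleucine
C00407	Isoleucine
C00041	L-Alanine
C00041	Alanine
C00099	beta-Alanine
C00099	β-Alanine
C00099	3-Aminopropanoate
C00149	(S)-Malate
C00149	L-Malic acid
C00149	Malate
C00091	Succinyl-CoA
C00091	Succinyl coenzyme A
C00068	Thiamin diphosphate
C00068	Thiamine diphosphate
C00068	ThPP
C00777	Retinoate
C00777	Retinoic acid
C00718	Amylopectin
C00025	L-Glutamate
C00025	Glutamate
C00025	Glutamic acid
C00049	L-Aspartate
C00049	Aspartic acid
C00022	Pyruvate
C00022	Pyruvic acid
C00042	Succinate
C00042	Succinic acid
C00122	Fumarate
C00122	Fumaric acid
C00036	Oxaloacetate
C00036	Oxalacetic acid
C00158	Citrate
C00158	Citric acid
C00024	Acetyl-CoA
C00024	Acetyl coenzyme A
C00550	Sphingomyelin
C00550	SM
C00346	Ethanolamine phosphate
C00346	Phosphoethanolamine
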