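gly_ser_thr	Glycine, serine and threonine metabolism (demo set)	Glycine	Serine	Threonine	Sarcosine	Creatine	Hydroxypyruvate	Choline
ala_asp_glu	Alanine, aspartate and glutamate metabolism (demo set)	Alanine	Glutamine	N-Acetylaspartate	N-Acetylglutamate	alpha-Ketoglutarate	Succinate	Fumarate	Citrate
phe_metabolism	Phenylalanine metabolism (demo set)	Phenylalanine	Phenylacetylglycine	Hippurate	Benzoate	ortho-Hydroxyphenylacetate
glyoxylate_dicarboxylate	Glyoxylate and dicarboxylate metabolism (demo set)	Citrate	cis-Aconitate	Glycine	Formate	Malate	Hydroxypyruvate
ketone_bodies	Synthesis and degradation of ketone bodies (demo set)	Acetoacetate	3-Hydroxybutyrate	Acetone
tca_cycle	Citrate cycle (demo set)	Citrate	cis-Aconitate	alpha-Ketoglutarate	Succinate	Fumarate	Malate
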