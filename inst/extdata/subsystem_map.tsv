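section_label	subsystem
Amino acids biosynthesis	AAB
Aminoacyl-tRNA charging metabolic clusters	AAT
Carbohydrates and Cell structures biosynthesis	CHB
Cell structures biosynthesis	CSB
Cofactors, Prosthetic groups, Electron carriers biosynthesis	CPEB
Fatty acid and lipid biosynthesis	FALB
Metabolic regulators biosynthesis	OTR
Nucleosides and nucleotides biosynthesis	NNB
Alcohols degradation	OTR
Amino acids degradation	OTR
Aromatic compounds degradation	ACD
C1 Compounds utilization and assimilation	C1UA
Inorganic nutrients metabolism	INM
Secondary metabolites degradation	SMD
Macromolecule modification	OTR
Small molecule reactions	OTR
Protein-modification reactions	PMR
Generation of precursor metabolites and energy	GPME
RNA-reactions	RR
tRNA reactions	tRR
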