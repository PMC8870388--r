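mirna	gene	evidence
hsa-miR-138-5p	CEBPA	Luciferase reporter assay
hsa-miR-138-5p	FABP4	Luciferase reporter assay
hsa-miR-138-5p	LPL	Luciferase reporter assay
hsa-miR-138-5p	MMP3	Luciferase reporter assay
hsa-miR-138-5p	NFKB1	Luciferase reporter assay
hsa-miR-138-5p	SERPINE1	Luciferase reporter assay
hsa-miR-138-5p	PPARG	Luciferase reporter assay
hsa-miR-138-5p	TERT	Luciferase reporter assay
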