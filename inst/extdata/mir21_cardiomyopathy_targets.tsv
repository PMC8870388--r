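mirna	gene	evidence
miR-21-5p	ERBB2	Luciferase reporter assay
miR-21-5p	IGF1R	Luciferase reporter assay
miR-21-5p	IL1B	Luciferase reporter assay
miR-21-5p	MMP2	Luciferase reporter assay
miR-21-5p	MMP9	Luciferase reporter assay
miR-21-5p	PTX3	Luciferase reporter assay
miR-21-5p	SMARCA4	Luciferase reporter assay
miR-21-5p	TGFB1	Luciferase reporter assay
miR-21-5p	TLR3	Luciferase reporter assay
miR-21-5p	TPM1	Luciferase reporter assay
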