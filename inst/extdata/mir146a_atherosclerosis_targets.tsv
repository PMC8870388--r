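mirna	gene	evidence
miR-146a-5p	CCL5	Luciferase reporter assay
miR-146a-5p	CD40LG	Luciferase reporter assay
miR-146a-5p	CFH	Luciferase reporter assay
miR-146a-5p	CXCL12	Luciferase reporter assay
miR-146a-5p	ELAVL1	Luciferase reporter assay
miR-146a-5p	ICAM1	Luciferase reporter assay
miR-146a-5p	IL6	Luciferase reporter assay
miR-146a-5p	MIF	Luciferase reporter assay
miR-146a-5p	NFKB1	Luciferase reporter assay
miR-146a-5p	PLAUR	Luciferase reporter assay
miR-146a-5p	PTGS2	Luciferase reporter assay
miR-146a-5p	RHOA	Luciferase reporter assay
miR-146a-5p	ROCK1	Luciferase reporter assay
miR-146a-5p	S100A12	Luciferase reporter assay
miR-146a-5p	SPP1	Luciferase reporter assay
miR-146a-5p	TGFB1	Luciferase reporter assay
miR-146a-5p	TLR2	Luciferase reporter assay
miR-146a-5p	TLR4	Luciferase reporter assay
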