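rsid	gene	chromosome	position
rs5186	AGTR1	3	148742201
rs17244841	HMGCR	5	75347030
rs5918	ITGB3	17	47283364
rs3856806	PPARG	3	12434058
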