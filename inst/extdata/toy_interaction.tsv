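gene_a	gene_b	source_tag
MELK	MKI67	PPI-demo
MKI67	MELK	PPI-demo
MELK	TTK	PPI-demo
MELK	SF3B1	PPI-demo
MELK	PTGES3	PPI-demo
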