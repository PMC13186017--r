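kinase	kinase_site	target	target_site	source_tag
TTK	S436	MELK	S356	NetPred-demo
NEK4	S563	MELK	S356	NetPred-demo
CAMK2D	S472	MELK	S505	NetPred-demo
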