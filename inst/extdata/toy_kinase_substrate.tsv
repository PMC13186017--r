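kinase	substrate	site	source_tag
MELK	CDC25C	S216	PSP-demo
MARK2	MELK	S356	PSP-demo
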