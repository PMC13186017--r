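gene	source_tag
TTK	KIN-demo
CAMK2D	KIN-demo
NEK4	KIN-demo
MELK	KIN-demo
MARK2	KIN-demo
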