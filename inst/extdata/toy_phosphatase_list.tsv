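gene	source_tag
PTPN2	PHOS-demo
CDC25C	PHOS-demo
PTPN13	PHOS-demo
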