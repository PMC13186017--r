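pmid	dataset_id	condition_id	dataset_kind	gene_symbol	residue	position	loc_prob	ascore	fold_change	p_value
PMID0001	DS1	C01	differential	MELK	S	356	0.95	20	2	0.01
PMID0001	DS1	C02	differential	MELK	S	356	0.95	20	2	0.01
PMID0001	DS1	C03	differential	MELK	S	356	0.95	20	2	0.01
PMID0002	DS1	C01	differential	MELK	S	356	0.95	20	2	0.01
PMID0002	DS1	C02	differential	MELK	S	356	0.95	20	2	0.01
PMID0002	DS1	C03	differential	MELK	S	356	0.95	20	2	0.01
PMID0003	DS1	C01	differential	MELK	S	356	0.95	20	0.5	0.01
PMID0003	DS1	C02	differential	MELK	S	356	0.95	20	0.5	0.01
PMID0003	DS1	C03	differential	MELK	S	356	0.95	20	0.5	0.01
PMID0004	DS1	C01	differential	MELK	S	356	0.95	20	0.5	0.01
PMID0004	DS1	C02	differential	MELK	S	356	0.95	20	0.5	0.01
PMID0004	DS1	C03	differential	MELK	S	356	0.95	20	0.5	0.01
PMID0001	DS1	C01	differential	MELK	S	505	0.95	20	2	0.01
PMID0001	DS1	C02	differential	MELK	S	505	0.95	20	2	0.01
PMID0001	DS1	C03	differential	MELK	S	505	0.95	20	2	0.01
PMID0002	DS1	C01	differential	MELK	S	505	0.95	20	2	0.01
PMID0002	DS1	C02	differential	MELK	S	505	0.95	20	2	0.01
PMID0002	DS1	C03	differential	MELK	S	505	0.95	20	2	0.01
PMID0003	DS1	C01	differential	MELK	S	505	0.95	20	0.5	0.01
PMID0003	DS1	C02	differential	MELK	S	505	0.95	20	0.5	0.01
PMID0003	DS1	C03	differential	MELK	S	505	0.95	20	0.5	0.01
PMID0004	DS1	C01	differential	MELK	S	505	0.95	20	0.5	0.01
PMID0004	DS1	C02	differential	MELK	S	505	0.95	20	0.5	0.01
PMID0004	DS1	C03	differential	MELK	S	505	0.95	20	0.5	0.01
PMID0001	DS1	C01	differential	MELK	S	529	0.95	20	2	0.01
PMID0001	DS1	C02	differential	MELK	S	529	0.95	20	2	0.01
PMID0001	DS1	C03	differential	MELK	S	529	0.95	20	2	0.01
PMID0002	DS1	C01	differential	MELK	S	529	0.95	20	2	0.01
PMID0003	DS1	C01	differential	MELK	S	529	0.95	20	0.5	0.01
PMID0003	DS1	C02	differential	MELK	S	529	0.95	20	0.5	0.01
PMID0003	DS1	C03	differential	MELK	S	529	0.95	20	0.5	0.01
PMID0004	DS1	C01	differential	MELK	S	529	0.95	20	0.5	0.01
PMID0004	DS1	C02	differential	MELK	S	529	0.95	20	1	0.5
PMID0001	DS1	C01	differential	MELK	T	460	0.95	20	0.5	0.01
PMID0001	DS1	C02	differential	MELK	T	460	0.95	20	0.5	0.01
PMID0001	DS1	C03	differential	MELK	T	415	0.95	20	2	0.01
PMID0001	DS1	C03	differential	MELK	T	415	0.95	20	0.5	0.01
PMID0001	DS1	C01	differential	KIAA0175	S	356	0.95	20	2	0.01
PMID0002	DS1	C02	differential	MELK	S	431	0.5	20	2	0.01
PMID0002	DS1	C02	differential	MELK	T	478	0.95	5	2	0.01
PMID0001	DS1	C01	differential	MKI67	T	2085	0.95	20	2	0.01
PMID0001	DS1	C02	differential	MKI67	T	2085	0.95	20	2	0.01
PMID0001	DS1	C03	differential	MKI67	T	2085	0.95	20	2	0.01
PMID0002	DS1	C01	differential	MKI67	T	2085	0.95	20	2	0.01
PMID0002	DS1	C02	differential	MKI67	T	2085	0.95	20	2	0.01
PMID0002	DS1	C03	differential	MKI67	T	2085	0.95	20	2	0.01
PMID0003	DS1	C01	differential	MKI67	T	2085	0.95	20	0.5	0.01
PMID0003	DS1	C02	differential	MKI67	T	2085	0.95	20	0.5	0.01
PMID0003	DS1	C03	differential	MKI67	T	2085	0.95	20	0.5	0.01
PMID0004	DS1	C01	differential	MKI67	T	2085	0.95	20	0.5	0.01
PMID0004	DS1	C02	differential	MKI67	T	2085	0.95	20	0.5	0.01
PMID0004	DS1	C03	differential	MKI67	T	2085	0.95	20	0.5	0.01
PMID0001	DS1	C01	differential	TTK	S	436	0.95	20	2	0.01
PMID0001	DS1	C02	differential	TTK	S	436	0.95	20	2	0.01
PMID0001	DS1	C03	differential	TTK	S	436	0.95	20	2	0.01
PMID0002	DS1	C01	differential	TTK	S	436	0.95	20	2	0.01
PMID0002	DS1	C02	differential	TTK	S	436	0.95	20	2	0.01
PMID0002	DS1	C03	differential	TTK	S	436	0.95	20	2	0.01
PMID0003	DS1	C01	differential	TTK	S	436	0.95	20	0.5	0.01
PMID0003	DS1	C02	differential	TTK	S	436	0.95	20	0.5	0.01
PMID0003	DS1	C03	differential	TTK	S	436	0.95	20	0.5	0.01
PMID0001	DS1	C01	differential	SF3B1	T	303	0.95	20	2	0.01
PMID0001	DS1	C02	differential	SF3B1	T	303	0.95	20	2	0.01
PMID0002	DS1	C01	differential	SF3B1	T	303	0.95	20	2	0.01
PMID0002	DS1	C02	differential	SF3B1	T	303	0.95	20	2	0.01
PMID0002	DS1	C03	differential	SF3B1	T	303	0.95	20	2	0.01
PMID0004	DS1	C01	differential	SF3B1	T	303	0.95	20	0.5	0.01
PMID0004	DS1	C02	differential	SF3B1	T	303	0.95	20	0.5	0.01
PMID0004	DS1	C03	differential	SF3B1	T	303	0.95	20	0.5	0.01
PMID0001	DS1	C01	differential	CDC25C	S	216	0.95	20	2	0.01
PMID0001	DS1	C02	differential	CDC25C	S	216	0.95	20	2	0.01
PMID0001	DS1	C03	differential	CDC25C	S	216	0.95	20	2	0.01
PMID0002	DS1	C01	differential	CDC25C	S	216	0.95	20	2	0.01
PMID0002	DS1	C02	differential	CDC25C	S	216	0.95	20	2	0.01
PMID0002	DS1	C03	differential	CDC25C	S	216	0.95	20	2	0.01
PMID0003	DS1	C01	differential	CDC25C	S	216	0.95	20	0.5	0.01
PMID0003	DS1	C02	differential	CDC25C	S	216	0.95	20	0.5	0.01
PMID0003	DS1	C03	differential	CDC25C	S	216	0.95	20	0.5	0.01
PMID0004	DS1	C01	differential	CDC25C	S	216	0.95	20	0.5	0.01
PMID0004	DS1	C02	differential	CDC25C	S	216	0.95	20	0.5	0.01
PMID0004	DS1	C03	differential	CDC25C	S	216	0.95	20	0.5	0.01
PMID0001	DS1	C01	differential	CAMK2D	S	472	0.95	20	0.5	0.01
PMID0001	DS1	C02	differential	CAMK2D	S	472	0.95	20	0.5	0.01
PMID0001	DS1	C03	differential	CAMK2D	S	472	0.95	20	0.5	0.01
PMID0002	DS1	C01	differential	CAMK2D	S	472	0.95	20	0.5	0.01
PMID0002	DS1	C02	differential	CAMK2D	S	472	0.95	20	0.5	0.01
PMID0002	DS1	C03	differential	CAMK2D	S	472	0.95	20	0.5	0.01
PMID0003	DS1	C01	differential	CAMK2D	S	472	0.95	20	2	0.01
PMID0003	DS1	C02	differential	CAMK2D	S	472	0.95	20	2	0.01
PMID0003	DS1	C03	differential	CAMK2D	S	472	0.95	20	2	0.01
PMID0004	DS1	C01	differential	CAMK2D	S	472	0.95	20	2	0.01
PMID0004	DS1	C02	differential	CAMK2D	S	472	0.95	20	2	0.01
PMID0004	DS1	C03	differential	CAMK2D	S	472	0.95	20	2	0.01
PMID0001	DS1	C01	differential	PTPN2	S	304	0.95	20	2	0.01
PMID0001	DS1	C02	differential	PTPN2	S	304	0.95	20	2	0.01
PMID0001	DS1	C03	differential	PTPN2	S	304	0.95	20	2	0.01
PMID0002	DS1	C01	differential	PTPN2	S	304	0.95	20	2	0.01
PMID0002	DS1	C02	differential	PTPN2	S	304	0.95	20	2	0.01
PMID0002	DS1	C03	differential	PTPN2	S	304	0.95	20	2	0.01
PMID0003	DS1	C01	differential	PTPN2	S	304	0.95	20	0.5	0.01
PMID0003	DS1	C02	differential	PTPN2	S	304	0.95	20	0.5	0.01
PMID0003	DS1	C03	differential	PTPN2	S	304	0.95	20	0.5	0.01
PMID0004	DS1	C01	differential	PTPN2	S	304	0.95	20	0.5	0.01
PMID0004	DS1	C02	differential	PTPN2	S	304	0.95	20	0.5	0.01
PMID0004	DS1	C03	differential	PTPN2	S	304	0.95	20	0.5	0.01
PMID0001	DS1	C01	differential	PTGES3	S	85	0.95	20	0.5	0.01
PMID0001	DS1	C02	differential	PTGES3	S	85	0.95	20	0.5	0.01
PMID0002	DS1	C01	differential	PTGES3	S	85	0.95	20	0.5	0.01
PMID0002	DS1	C02	differential	PTGES3	S	85	0.95	20	0.5	0.01
PMID0002	DS1	C03	differential	PTGES3	S	85	0.95	20	0.5	0.01
PMID0004	DS1	C01	differential	PTGES3	S	85	0.95	20	2	0.01
PMID0004	DS1	C02	differential	PTGES3	S	85	0.95	20	2	0.01
PMID0004	DS1	C03	differential	PTGES3	S	85	0.95	20	2	0.01
PMID0001	DS1	C01	differential	FLNB	S	2107	0.95	20	2	0.01
PMID0001	DS1	C02	differential	FLNB	S	2107	0.95	20	0.5	0.01
PMID0001	DS1	C03	differential	FLNB	S	2107	0.95	20	2	0.01
PMID0002	DS1	C01	differential	FLNB	S	2107	0.95	20	0.5	0.01
PMID0002	DS1	C02	differential	FLNB	S	2107	0.95	20	2	0.01
PMID0002	DS1	C03	differential	FLNB	S	2107	0.95	20	0.5	0.01
PMID0003	DS1	C01	differential	FLNB	S	2107	0.95	20	2	0.01
PMID0003	DS1	C02	differential	FLNB	S	2107	0.95	20	0.5	0.01
PMID0003	DS1	C03	differential	FLNB	S	2107	0.95	20	2	0.01
PMID0004	DS1	C01	differential	FLNB	S	2107	0.95	20	0.5	0.01
PMID0004	DS1	C02	differential	FLNB	S	2107	0.95	20	2	0.01
PMID0004	DS1	C03	differential	FLNB	S	2107	0.95	20	0.5	0.01
PMID0005	DS1	C01	profile	MELK	S	356	0.95	NA	NA	NA
PMID0006	DS1	C01	profile	MELK	S	356	0.95	NA	NA	NA
PMID0007	DS1	C01	profile	MELK	S	356	0.95	NA	NA	NA
PMID0005	DS1	C01	profile	MELK	S	505	0.95	NA	NA	NA
PMID0006	DS1	C01	profile	MELK	S	505	0.95	NA	NA	NA
PMID0005	DS1	C01	profile	MELK	S	529	0.95	NA	NA	NA
PMID0006	DS1	C01	profile	MELK	S	529	0.95	NA	NA	NA
PMID0005	DS1	C01	profile	MELK	T	460	0.95	NA	NA	NA
PMID0007	DS1	C01	profile	MELK	S	162	0.6	NA	NA	NA
PMID0005	DS1	C01	profile	MKI67	T	2085	0.95	NA	NA	NA
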