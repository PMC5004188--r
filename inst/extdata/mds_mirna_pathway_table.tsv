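mirna	style	fold_change	gene	pathway
miR-148a	Down	-7.70	TEK	PI3K-Akt signaling pathway
miR-148a	Down	-7.70	ITGA9	PI3K-Akt signaling pathway
miR-148a	Down	-7.70	KIT	PI3K-Akt signaling pathway
miR-148a	Down	-7.70	HMGA2	Transcriptional misregulation in cancer
miR-145	Down	-2.96	HHEX	Transcriptional misregulation in cancer
miR-145	Down	-2.96	MEIS1	Transcriptional misregulation in cancer
miR-200c	Down	-2.82	EFNA1	PI3K-Akt signaling pathway
miR-200c	Down	-2.82	KLF3	Transcriptional misregulation in cancer
miR-195	Up	6.04	BDNF	MAPK signaling pathway
miR-195	Up	6.04	CDC25B	MAPK signaling pathway
miR-195	Up	6.04	DLL1	Notch signaling pathway
miR-195	Up	6.04	MRAS	MAPK signaling pathway
miR-17	Up	3.32	CAMK2D	Calcium signaling pathway
miR-19a	Up	5.85	MAML1	Notch signaling pathway
miR-19a	Up	5.85	SLC8A1	Calcium signaling pathway
miR-19a	Up	5.85	THBS1	Proteoglycans in cancer
miR-19a	Up	5.85	TNF	MAPK signaling pathway
miR-19a	Up	5.85	TNFRSF1B	Adipocytokine signaling pathway
miR-19a	Up	5.85	ACSL1	Adipocytokine signaling pathway
miR-19a	Up	5.85	EDNRB	Calcium signaling pathway
miR-19b	Up	2.53	CALM1	Calcium signaling pathway
miR-19b	Up	2.53	TNF	Proteoglycans in cancer
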