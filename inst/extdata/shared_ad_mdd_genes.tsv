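gene_id	symbol	gene_name	sources
5243	ABCB1	ATP binding cassette subfamily B member 1	literature,disgenet
1636	ACE	Angiotensin I converting enzyme	literature,disgenet
155	ADRB3	Adrenoceptor beta 3	literature,disgenet
348	APOE	Apolipoprotein E	literature,disgenet
406	ARNTL	Aryl hydrocarbon receptor nuclear translocator like	literature
540	ATP7B	ATPase copper transporting beta	literature,disgenet
613	BCR	BCR, RhoGEF and GTPase activating protein	literature,disgenet
627	BDNF	Brain derived neurotrophic factor	literature,disgenet
6347	CCL2	C-C motif chemokine ligand 2	literature,disgenet
1029	CDKN2A	Cyclin dependent kinase inhibitor 2A	literature,disgenet
89832	CHRFAM7A	CHRNA7 (exons 5–10) and FAM7A (exons A-E) fusion	literature
9575	CLOCK	Clock circadian regulator	literature,disgenet
26047	CNTNAP2	Contactin associated protein 2	literature,disgenet
1312	COMT	catechol-O-methyltransferase	literature,disgenet
1392	CRH	Corticotropin releasing hormone	disgenet
1565	CYP2D6	Cytochrome P450 family 2 subfamily D member 6	literature,disgenet
267012	DAOA	D-amino acid oxidase activator	literature,disgenet
1621	DBH	Dopamine beta-hydroxylase	literature,disgenet
27185	DISC1	Disrupted in schizophrenia 1	literature,disgenet
1740	DLG2	Disks large MAGUK scaffold protein 2	literature,disgenet
1742	DLG4	Disks large MAGUK scaffold protein 4	literature,disgenet
1815	DRD4	Dopamine receptor D4	literature,disgenet
5610	EIF2AK2	Eukaryotic translation initiation factor 2 alpha kinase 2	literature
2099	ESR1	Estrogen receptor 1	literature,disgenet
2100	ESR2	Estrogen receptor 2	literature,disgenet
79068	FTO	Alpha-ketoglutarate dependent dioxygenase	literature
2692	GHRHR	Growth hormone releasing hormone receptor	literature
2784	GNB3	G protein subunit beta 3	literature,disgenet
2904	GRIN2B	Glutamate ionotropic receptor NMDA type subunit 2B	literature
2932	GSK3B	Glycogen synthase kinase 3 beta	literature,disgenet
3091	HIF1A	Hypoxia inducible factor 1 subunit alpha	literature,disgenet
3240	HP	Haptoglobin	literature,disgenet
3308	HSPA4	Heat shock protein family A (Hsp70) member 4	literature,disgenet
3356	HTR2A	5-hydroxytryptamine receptor 2A	literature,disgenet
3362	HTR6	5-hydroxytryptamine receptor 6	literature
3586	IL10	Interleukin 10	literature,disgenet
3553	IL1B	Interleukin 1 beta	literature,disgenet
90865	IL33	Interleukin 33	literature,disgenet
3569	IL6	Interleukin 6	literature,disgenet
3952	LEP	Leptin	disgenet
4035	LRP1	LDL receptor related protein 1	literature,disgenet
7804	LRP8	LDL receptor related protein 8	literature,disgenet
4128	MAOA	Monoamine oxidase A	literature,disgenet
4129	MAOB	Monoamine oxidase B	disgenet
4133	MAP2	Microtubule associated protein 2	disgenet
9175	MAP3K13	Mitogen-activated protein kinase 13	literature
4353	MPO	Myeloperoxidase	literature,disgenet
4524	MTHFR	Methylenetetrahydrofolate reductase	literature,disgenet
4599	MX1	MX dynamin like GTPase 1	literature
4803	NGF	Nerve growth factor	literature,disgenet
4852	NPY	Neuropeptide Y	literature,disgenet
4908	NTF3	Neurotrophin 3	literature,disgenet
4915	NTRK2	Neurotrophic receptor tyrosine kinase 2	literature,disgenet
84547	PGBD1	piggyBac transposable element derived 1	literature
65018	PINK1	PTEN induced kinase 1	literature,disgenet
5337	PLD1	Phospholipase D1	literature
5444	PON1	Paraoxonase 1	literature
5743	PTGS2	Prostaglandin-endoperoxide synthase 2	literature,disgenet
5649	RELN	Reelin	literature,disgenet
6285	S100B	S100 calcium binding protein B	literature,disgenet
9037	SEMA5A	Semaphorin 5A	literature
10280	SIGMAR1	Sigma non-opioid intracellular receptor 1	literature
23411	SIRT1	Sirtuin 1	literature
6531	SLC6A3	Solute carrier family 6 member 3	literature
6532	SLC6A4	solute carrier family 6 member 4	literature,disgenet
6648	SOD2	Superoxide dismutase 2	literature,disgenet
6671	SP4	Sp4 transcription factor	literature
6688	SPI1	Spi-1 proto-oncogene	literature
6750	SST	Somatostatin	literature,disgenet
7024	TFCP2	Transcription factor CP2	literature,disgenet
7040	TGFB1	Transforming growth factor beta 1	literature
7124	TNF	Tumor necrosis factor	literature,disgenet
10452	TOMM40	Translocase of outer mitochondrial membrane 40	literature,disgenet
7157	TP53	Tumor protein p53	literature
7422	VEGFA	Vascular endothelial growth factor A	literature,disgenet
7434	VIPR2	Vasoactive intestinal peptide receptor 2	literature
91752	ZNF804A	Zinc finger protein 804A	literature
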