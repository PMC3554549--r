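gene_set	source	p_bomp	p_burden	p_position	fdr_published	synaptic_genes	set_size
MAPK SIGNALING PATHWAY	KEGG	0.0065	1.0000	0.0043	0.0949	68	267
AXON GUIDANCE	Reactome	0.0162	0.5847	0.0137	0.0949	71	161
NEUROLOGICAL SYSTEM PROCESS	GO	0.0274	0.2787	0.0273	0.0949	75	377
METABOLISM OF PROTEINS	Reactome	0.0299	0.3437	0.0272	0.0949	96	215
NEUROACTIVE LIGAND RECEPTOR INTERACTION	KEGG	0.0309	0.8490	0.0259	0.0949	21	272
HUNTINGTONS DISEASE	KEGG	0.0312	0.5408	0.0266	0.0949	77	185
CALCIUM SIGNALING PATHWAY	KEGG	0.0332	0.4796	0.0303	0.0949	51	178
POST TRANSLATIONAL PROTEIN MODIFICATION	GO	0.0635	0.4031	0.0620	0.1587	87	462
NERVOUS SYSTEM DEVELOPMENT	GO	0.0744	0.8912	0.0674	0.1654	88	382
SIGNALLING BY NGF	Reactome	0.1290	0.8393	0.1139	0.2317	71	215
GNRH SIGNALING PATHWAY	KEGG	0.1313	0.7485	0.1109	0.2317	34	101
OXIDATIVE PHOSPHORYLATION	KEGG	0.1390	0.4222	0.1263	0.2317	66	135
ALZHEIMERS DISEASE	KEGG	0.2164	0.7012	0.1904	0.3151	76	169
INTRACELLULAR SIGNALING CASCADE	GO	0.2267	0.7489	0.2174	0.3151	120	648
NEUROTROPHIN SIGNALING PATHWAY	KEGG	0.2363	0.7995	0.2031	0.3151	45	126
CHEMOKINE SIGNALING PATHWAY	KEGG	0.2667	0.6638	0.2464	0.3272	50	190
WNT SIGNALING PATHWAY	KEGG	0.2781	0.7009	0.2519	0.3272	38	151
REGULATION OF GENE EXPRESSION IN BETA CELLS	Reactome	0.3401	0.0877	0.4571	0.3779	60	101
MITOCHONDRION	GO	0.4315	0.9727	0.4047	0.4542	117	339
PARKINSONS DISEASE	KEGG	0.7893	0.3087	0.8111	0.7893	62	133
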