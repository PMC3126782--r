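# published per-library mapping and expression summary for the six adult
# A. gambiae chemosensory-appendage RNA-seq libraries
# reads = raw single-end 43 bp reads; mapped_reads = reads mapped anywhere;
# transcriptome_reads = weighted reads mapped to annotated transcripts;
# gene expression summary computed over genes with detectable expression
tissue	reads	mapped_reads	mapped_pct	transcriptome_reads	transcriptome_pct	nuclear_genome_reads	mito_genome_reads	gene_count	median_rpkm	mean_rpkm	sd_rpkm
female_bodies	27877821	25358733	90.96	16606092	59.57	14680019	263602	12145	8.87	59.74	543.15
female_antennae	25980364	24123025	92.85	14617276	56.26	15280026	80727	11722	9.38	59.22	732.65
female_palps	27449612	25984839	94.66	15293125	55.71	16700334	420897	12297	10.37	56.44	496.05
male_bodies	31876060	30226447	94.82	17603111	55.22	16016349	2408310	12253	8.34	54.01	424.05
male_antennae	33950770	32144101	94.68	18231088	53.70	21427148	241273	11986	10.34	46.01	229.14
male_palps	35705184	33339629	93.37	22596709	63.29	17625684	536952	12146	8.40	49.14	286.49
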