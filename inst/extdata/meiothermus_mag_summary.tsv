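mag_id	abundance_pct	abundance_class	est_genome_size_mbp	n_protein_genes	replication_rate	total_snvs
S-30	1.33	abundant	3.56	3278	3.02	1473
S-65	0.14	rare	3.25	2953	2.72	5016
S-132	0.72	rare	3.71	3526	1.00	15560
D-30	0.76	rare	2.82	2656	1.06	6942
D-65	1.22	abundant	3.12	2949	1.04	1335
D-132	9.17	abundant	3.00	2869	1.01	2589
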