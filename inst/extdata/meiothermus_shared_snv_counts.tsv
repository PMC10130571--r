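mag_set	kind	n_same_site	n_same_substitution	ani_shared_contigs	ani_unshared_contigs
S-30,D-30	pair	2	0	NA	81.0
S-65,D-65	pair	0	0	NA	81.8
S-132,D-132	pair	3	2	95.4	81.5
S-65,S-132	pair	259	219	100	83.5
D-65,D-132	pair	62	44	100	83.9
D-30,D-65	pair	25	11	98.1	82.5
D-30,S-132	pair	73	9	85.6	81.4
S-30,S-65	pair	25	22	100	86.6
S-30,D-132	pair	8	0	NA	81.4
S-30,D-65	pair	37	0	NA	81.5
S-30,S-132	pair	173	148	100	84.1
D-65,S-132	pair	34	20	91.4	82.7
D-30,S-65	pair	15	3	93.8	80.9
D-30,D-132	pair	27	15	98.4	83.5
S-65,D-132	pair	1	0	NA	81.4
D-30,D-65,D-132	triplet	10	2	NA	NA
S-30,S-65,S-132	triplet	5	4	NA	NA
S-30,D-65,D-132	triplet	0	0	NA	NA
D-30,S-65,S-132	triplet	1	0	NA	NA
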