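mag_id	D-132	D-65	D-30	S-132	S-65	S-30
D-132	1.00	1.00	0.42	0.44	0.86	0.43
D-65	1.00	1.00	0.41	0.43	0.87	0.42
D-30	0.42	0.41	1.00	0.88	0.44	0.87
S-132	0.44	0.43	0.88	1.00	0.43	1.00
S-65	0.86	0.87	0.44	0.43	1.00	0.44
S-30	0.43	0.42	0.87	1.00	0.44	1.00
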