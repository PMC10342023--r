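dataset	stage	events	substrates	proteases
pdb_training	extracted	4576	2062	457
pdb_training	structure_assigned	1499	585	256
pdb_training	mapped	777	323	183
pdb_training	curated	445	190	130
alphafold_training	structure_assigned	3168	1209	317
alphafold_training	mapped	2925	1209	317
alphafold_training	curated	2918	1205	314
merops_testing	extracted	213	129	3
merops_testing	structure_assigned	81	48	3
merops_testing	mapped	43	27	3
merops_testing	curated	28	18	3
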