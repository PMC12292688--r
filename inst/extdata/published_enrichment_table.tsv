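enrichment_fdr	n_genes	pathway_genes	fold_enrichment	pathways
5.7e-08	6	50	50.7	Cholesterol metabolism
2.0e-05	4	41	41.2	Bladder cancer
2.3e-04	3	31	40.9	Antifolate resistance
2.9e-03	2	22	38.4	Arginine biosynthesis
1.3e-10	9	100	38	AGE-RAGE signaling pathway in diabetic complications
3.5e-05	4	49	34.5	Malaria
3.2e-04	3	37	34.2	African trypanosomiasis
4.0e-07	6	76	33.3	Pertussis
9.3e-11	10	138	30.6	Fluid shear stress and atherosclerosis
4.7e-03	2	29	29.1	Linoleic acid metabolism
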