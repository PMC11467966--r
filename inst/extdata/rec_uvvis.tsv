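aldehyde	amine	conc_uM	epsilon_L_mol_cm	k1_1e2_L_mol_s	k1_u_1e2	k_minus1_1e6_s	k_minus1_u_1e6	Keq_1e3_L_mol	Keq_u_1e3	method	aggregation
3	4	100	NA	NA	NA	NA	NA	NA	NA	no_reaction	NA
3	5	100	2200	950	30	8.3	5.1	1600	1300	free_fit	per_replicate_mean
3	6	100	4200	1030	30	365	6	28	1	free_fit	per_replicate_mean
3	7	100	8600	69	3	57	3	12.0	0.7	free_fit	per_replicate_mean
3	8	100	9700	400	20	1.1	0.3	3700	1100	constrained_fit	global_fit
3	9	50	14200	75	4	11	8	87	60	constrained_fit	per_replicate_mean
2	5	500	950	5.8	0.2	52	25	1.3	0.6	free_fit	per_replicate_mean
2	6	100	2100	9.9	2.2	450	70	0.22	0.06	free_fit	per_replicate_mean
2	7	500	1870	0.9	0.2	91	12	0.10	0.01	free_fit	per_replicate_mean
2	8	100	8700	12	1	315	11	0.39	0.02	free_fit	per_replicate_mean
2	9	50	7200	5.9	0.03	NA	NA	NA	NA	irreversible_fit	per_replicate_mean
1	5	100	2850	95	8	106	6	9.0	0.5	free_fit	per_replicate_mean
1	6	100	4750	63	2	160	1	3.9	0.1	free_fit	per_replicate_mean
1	7	100	11100	12.4	0.3	57	1	2.2	0.1	free_fit	per_replicate_mean
1	8	100	10200	57.0	1.5	76	2	7.5	0.4	free_fit	per_replicate_mean
1	9	50	20500	5.1	0.3	5.2	3.4	13	7	free_fit	per_replicate_mean
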