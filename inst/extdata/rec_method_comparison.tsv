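method	imine	salt_total_mM	conc0_mM	k1_1e2_L_mol_s	k1_u_1e2	k_minus1_1e6_s	k_minus1_u_1e6	Keq_1e3_L_mol	Keq_u_1e3	aggregation
uvvis	2+5	159	0.5	5.8	0.2	52	25	1.3	0.6	per_replicate_mean
uvvis	2+7	159	0.5	0.9	0.2	91	12	0.10	0.01	per_replicate_mean
nmr	2+5	57	5	0.5	0.001	29	1	0.19	0.006	per_replicate_mean
nmr	2+7	57	24	0.09	0.003	119	9	0.007	0.001	single_replicate_se
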