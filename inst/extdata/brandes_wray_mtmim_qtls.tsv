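# Published multitrait multiple-interval-mapping QTL summary for the
# Brandes x Wray sweet sorghum RIL population evaluated in three trials
# (T1, T2, T3). Effects are additive for the +1/-1 genotype score (positive =
# Brandes allele increases the trait); PVE in %; 'sur' marks per-trial
# effects pruned by the seemingly-unrelated-regression step.
trait	qtl	chrom	pos_cM	marker_bp	lod	eff_T1	pve_T1	eff_T2	pve_T2	eff_T3	pve_T3
FLW	1	1	30.00	11093514	2.44	-1.69	2.80	sur	sur	sur	sur
FLW	2	1	198.00	71594007	5.85	2.72	8.95	5.27	3.79	4.63	3.31
FLW	3	6	0.00	382696	9.89	-4.81	25.46	-14.05	24.46	-10.96	16.86
FLW	4	6	42.65	4049408	18.74	6.83	32.45	27.69	60.03	22.73	45.89
FLW	5	10	74.91	53882121	4.29	-2.04	2.72	-7.90	4.58	-8.09	5.45
HGH	1	1	162.83	64727343	4.98	17.99	4.91	21.66	3.73	sur	sur
HGH	2	3	92.14	69453408	3.75	sur	sur	sur	sur	-21.52	4.51
HGH	3	6	67.00	44949491	9.57	sur	sur	38.38	9.16	sur	sur
HGH	4	9	64.70	49204605	8.09	-32.69	12.03	-25.59	3.86	-31.07	7.77
HGH	5	10	70.00	48678282	7.08	-25.17	7.48	-40.70	10.25	-22.77	4.38
FBY	1	1	206.69	73162697	3.67	4.39	6.23	3.97	2.79	sur	sur
FBY	2	6	73.91	46121015	7.97	sur	sur	10.88	10.12	12.05	6.14
FBY	3	10	71.00	48678282	7.77	-7.58	8.98	-8.66	6.40	-14.49	8.87
JUC	1	1	0.00	1581214	3.87	sur	sur	1.54	5.76	1.32	3.07
JUC	2	6	88.00	48478843	4.53	sur	sur	-1.91	4.39	-2.76	6.59
JUC	3	9	62.40	48103357	4.98	sur	sur	2.76	7.75	2.35	4.03
BRX	1	1	0.00	1581214	5.78	-1.30	5.38	-1.09	4.98	-1.31	6.24
BRX	2	3	75.14	65279548	8.54	-3.14	12.94	-1.70	4.97	-1.49	3.31
BRX	3	6	61.00	42731400	6.02	sur	sur	2.18	8.83	sur	sur
BRX	4	6	113.18	52779223	4.00	0.96	2.01	sur	sur	1.46	5.30
BRX	5	9	67.00	49406423	7.30	-2.62	9.11	-1.99	6.90	-1.67	4.20
SUC	1	1	1.71	2709413	7.10	-1.49	7.83	-1.05	4.75	-1.43	7.09
SUC	2	3	51.00	58433131	10.52	-3.27	15.25	-1.37	3.27	-2.23	7.00
SUC	3	6	71.64	45898926	5.78	1.25	2.45	2.10	8.45	sur	sur
SUC	4	6	122.80	54328118	2.87	sur	sur	sur	sur	1.22	4.09
SUC	5	9	65.26	49406423	7.29	-2.42	8.66	-2.05	7.58	-1.72	4.35
RSU	1	1	0.00	1553727	2.35	sur	sur	sur	sur	0.10	4.20
RSU	2	3	45.22	57882869	9.02	0.52	10.71	sur	sur	0.21	8.63
RSU	3	4	0.00	273007	4.13	0.29	6.73	sur	sur	sur	sur
FIB	1	3	112.04	73490974	3.98	1.12	3.62	0.75	5.17	0.77	5.54
FIB	2	6	70.04	45740799	3.38	sur	sur	sur	sur	0.90	5.16
FIB	3	8	92.62	52308546	3.28	sur	sur	0.49	2.98	0.62	4.82
FIB	4	9	42.00	6770591	2.62	1.49	4.53	sur	sur	sur	sur
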