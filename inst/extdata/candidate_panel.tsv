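gene	cancer_median_rpkm	fold_change	percentile_ratio	blood_p95_geo	blood_p95_gtex	note
NDUFA4L2	701	145	1.06	0.16	0.15	
EGLN3	174	23.2	0.93	0.72	0.62	
CA9	117	1218	3.74	1	0.13	
CCND1	138	4.34	0.58	0.58	0.37	
CAV2	110	3.98	0.69	0.43	0.43	
ESM1	92.5	12.4	0.6	0.77	0.2	
PPP1R3C	20.1	3.66	0.54	0.03	0.67	
STC2	19.1	22.3	1.33	0	0.07	
NPTX2	18.4	150	1.48	0.07	0.13	
ANGPT2	17.1	10.4	0.54	0.11	0.08	
DGCR5	15.2	25.9	0.99	0.3	0.17	
DOCK6	13.2	2.08	0.51	0.26	0.68	
FABP6	11.9	91.3	1.18	0.62	0.85	
TMEM133	8.9	2.67	0.52	0.60	0.24	
LZTS1	8.8	15.54	0.52	0.26	0.25	
COX4I2	6.85	4.37	0.52	0.06	0.15	
KIAA1274	6.71	4.11	0.58	0.78	0.41	
LPIN3	6.14	2.29	0.54	0.12	0.17	
FKBP9L	6.11	1.32	0.51	0.71	0.14	
RAB42	5.90	5.47	1.02	0.17	0.49	
MET	112	2.08	0.36	0.07	0.1	
CDK18	85.4	5.29	0.28	1.21	0.85	
CP	79.7	21.3	0.11	0.89	0.4	
TMEM45A	62.9	2.43	0.71	0.13	2.31	
LOX	51.0	10.8	0.22	0.22	0.29	
GAL3ST1	49.4	8.14	0.3	0.15	0.11	
CYP2J2	49	39.3	0.27	0.65	0.2	
NOL3	44.1	10.6	1.36	1.98	2.47	
FBXO17	38.7	2.77	0.52	0.1	2	ambiguous
FABP7	19.9	974	0.22	0	0.05	
BARX2	19.1	6.01	0.27	0.42	0.04	
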