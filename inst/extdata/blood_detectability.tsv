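gene	tissue_confirmed	tissue_fold_change	mean_cq	cq_status
NDUFA4L2	yes	133	NA	above_ceiling
EGLN3	yes	25	26.1	measured
CA9	yes	1938	NA	above_ceiling
CCND1	yes	5	31.5	measured
CAV2	not_tested	NA	26.1	measured
ESM1	not_tested	NA	30.6	measured
PPP1R3C	yes	5	NA	above_ceiling
STC2	yes	3	NA	above_ceiling
NPTX2	yes	24	NA	above_ceiling
ANGPT2	yes	24	NA	above_ceiling
DOCK6	yes	1	NA	above_ceiling
FABP6	not_tested	NA	NA	above_ceiling
MET	not_tested	NA	NA	above_ceiling
CDK18	yes	2	27.6	measured
CP	yes	40	NA	above_ceiling
TMEM45A	yes	9	28.8	measured
LOX	not_tested	NA	30.7	measured
GAL3ST1	not_tested	NA	NA	above_ceiling
CYP2J2	yes	19	NA	above_ceiling
NOL3	not_tested	NA	29.8	measured
FABP7	not_tested	NA	32.5	measured
BARX2	yes	9	NA	above_ceiling
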