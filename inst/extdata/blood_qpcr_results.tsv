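gene	fold_change_signed	p_value	verdict
EGLN3	-1.26	0.215	ns
CCND1	-1.55	0.039	down
CAV2	1.16	0.497	ns
ESM1	-1.21	0.668	ns
CDK18	-2.10	0.001	down
TMEM45A	-1.04	0.734	ns
LOX	-1.31	0.668	ns
NOL3	-1.05	0.641	ns
FABP7	-1.13	0.671	ns
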