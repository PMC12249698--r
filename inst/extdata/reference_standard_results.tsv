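standard	variant_type	tp	fp	truth_n	negative_n	mean_depth	design_vaf
S800-1	SNV/INDEL	27	0	27	50	1000	0.02
S800-1	CNV	3	0	3	50	1000	0.02
S800-1	Fusion	6	0	6	50	1000	0.02
S800-2	SNV/INDEL	27	0	27	50	2000	0.005
S800-2	CNV	3	0	3	50	2000	0.005
S800-2	Fusion	6	0	6	50	2000	0.005
Tru-Q7	SNV/INDEL	39	0	40	50	993	0.0115
Tru-Q7	SNV/INDEL	37	0	40	50	560	0.0115
Tru-Q7+Tru-Q0	SNV/INDEL	34	0	40	50	794	0.006
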