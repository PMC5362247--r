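gene	primary_z	counter_z	fpkm_minus_dox	fpkm_plus_dox	validation_pct	fold_rescue
FOSB	3.86	0.66	0.16	8.59	54.7	75.17
RNASEL	3.71	-0.07	0.94	0.54	52.4	63.50
MYC	3.69	-0.29	29.87	696.89	63.9	62.60
FXN	3.67	-0.06	3.51	0.77	61.6	61.70
EAF1	3.63	-0.32	5.89	19.27	34.0	58.60
PHF20	3.39	0.77	4.93	1.36	38.3	44.93
NLGN2	3.36	-0.09	8.85	1.77	NA	43.17
TGS1	3.35	0.78	10.11	12.56	NA	43.10
HSD17B4	3.29	0.92	5.57	2.09	NA	39.97
ITPK1	3.28	1.1	1.41	0.44	NA	39.60
SGK196	3.19	0.23	4.64	2.52	NA	36.47
CDC20	3.15	-0.41	79.51	358.73	NA	33.87
QSOX1	3.15	0.19	7.54	4.37	NA	33.87
THOP1	3.06	0.1	11.19	3.34	NA	30.87
FBN2	3.04	-0.08	0.91	0.51	NA	30.37
APH1A	3.02	-0.33	15.96	4.79	NA	30.00
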