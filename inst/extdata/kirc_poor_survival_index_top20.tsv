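# curated top-20 immune-regulation gene index inputs for poor-survival KIRC
# mean_tumor_expr: mean FPKM over 38 poor-survival tumors
# fold_change: tumor vs matched adjacent normal, linear scale
gene	mean_tumor_expr	fold_change	published_index
LBP	102.86	82.72	8508.58
COL1A1	281.4	16.56	4659.98
FGA	119.28	38.54	4597.05
FGB	243.86	17.23	4201.71
C3	284.99	12.39	3531.03
FGG	111.66	23.23	2593.86
CD74	1027.66	2.45	2517.77
HLA-B	840.9	2.89	2430.20
ACTB	1465.75	1.5	2198.63
HLA-DRA	857.02	2.5	2142.55
HLA-A	700.9	2.72	1906.45
B2M	878.18	2.02	1773.92
C1QB	180.01	7.75	1395.08
ENPP3	62.94	20.35	1280.83
COL1A2	177.99	7.03	1251.27
C1QA	195.03	6.36	1240.39
C1QC	174.56	6.88	1200.97
HLA-DRB1	453.56	2.21	1002.37
COL3A1	206.08	4.47	921.18
HLA-C	484.89	1.82	882.50
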