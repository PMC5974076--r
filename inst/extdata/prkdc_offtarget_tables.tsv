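table	site_id	sample	pct_indels_mock	pct_indels_zfn	differential_printed
cultured_cells	On-target	Fibroblasts	0.05	18.02	17.97
cultured_cells	Off-target 1	Fibroblasts	0.66	0.73	0.07
cultured_cells	Off-target 2	Fibroblasts	0.10	0.21	0.11
cultured_cells	Off-target 3	Fibroblasts	0.02	0.11	0.09
cultured_cells	Off-target 4	Fibroblasts	0.11	0.10	-0.01
cultured_cells	Off-target 5	Fibroblasts	0.06	0.14	0.08
cultured_cells	Off-target 6	Fibroblasts	0.76	0.98	0.22
cultured_cells	Off-target 7	Fibroblasts	0.00	0.01	0.01
cultured_cells	Off-target 8	Fibroblasts	0.52	1.03	0.51
cultured_cells	Off-target 9	Fibroblasts	0.01	1.35	1.34
cultured_cells	On-target	HSPCs	0.08	0.60	0.52
cultured_cells	Off-target 1	HSPCs	0.08	0.53	0.45
cultured_cells	Off-target 2	HSPCs	0.08	0.16	0.08
cultured_cells	Off-target 3	HSPCs	0.00	0.00	0.00
cultured_cells	Off-target 4	HSPCs	0.02	0.03	0.01
cultured_cells	Off-target 5	HSPCs	0.04	0.03	-0.01
cultured_cells	Off-target 6	HSPCs	0.69	0.70	0.01
cultured_cells	Off-target 7	HSPCs	0.01	ND	ND
cultured_cells	Off-target 8	HSPCs	0.29	0.18	-0.11
cultured_cells	Off-target 9	HSPCs	0.00	ND	ND
mice	On-target	Mouse 3.2 thymus	1.23	46.03	44.80
mice	Off-target 1	Mouse 3.2 thymus	3.92	3.04	-0.88
mice	Off-target 2	Mouse 3.2 thymus	0.13	0.07	-0.07
mice	Off-target 3	Mouse 3.2 thymus	0.01	0.04	0.03
mice	Off-target 4	Mouse 3.2 thymus	0.05	0.05	0.00
mice	Off-target 5	Mouse 3.2 thymus	0.12	0.05	-0.07
mice	Off-target 6	Mouse 3.2 thymus	2.14	1.91	-0.23
mice	Off-target 7	Mouse 3.2 thymus	0.01	0.00	-0.01
mice	Off-target 8	Mouse 3.2 thymus	0.83	0.67	-0.16
mice	Off-target 9	Mouse 3.2 thymus	0.05	0.39	0.34
mice	Off-target 10	Mouse 3.2 thymus	0.95	0.76	-0.19
mice	On-target	Mouse 3.2 spleen CD8	1.23	68.06	66.83
mice	Off-target 1	Mouse 3.2 spleen CD8	3.92	3.91	-0.01
mice	Off-target 2	Mouse 3.2 spleen CD8	0.13	0.14	0.01
mice	Off-target 3	Mouse 3.2 spleen CD8	0.01	0.02	0.01
mice	Off-target 4	Mouse 3.2 spleen CD8	0.05	0.04	-0.01
mice	Off-target 5	Mouse 3.2 spleen CD8	0.12	0.08	-0.04
mice	Off-target 6	Mouse 3.2 spleen CD8	2.14	1.92	-0.22
mice	Off-target 7	Mouse 3.2 spleen CD8	0.01	0.00	-0.01
mice	Off-target 8	Mouse 3.2 spleen CD8	0.83	0.74	-0.10
mice	Off-target 9	Mouse 3.2 spleen CD8	0.05	0.04	-0.01
mice	Off-target 10	Mouse 3.2 spleen CD8	0.95	0.83	-0.12
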