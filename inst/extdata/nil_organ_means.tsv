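organ	family	genotype	mean_length_mm	se_length_mm	mean_width_mm	se_width_mm	printed_shape_index	printed_shape_se	n_plants
ovary	13S140	fs8.1	2.20	0.01	1.96	0.01	1.12	0.01	6
ovary	13S140	WT	1.93	0.02	1.95	0.01	0.99	0.01	6
ovary	13S117_118	fs8.1	2.12	0.02	1.96	0.03	1.08	0.02	6
ovary	13S117_118	WT	1.84	0.02	1.88	0.02	0.98	0.01	6
fruit	13S140	fs8.1	66.93	1.12	60.77	0.99	1.10	0.01	8
fruit	13S140	WT	59.53	0.84	62.71	0.61	0.96	0.01	8
fruit	13S117_118	fs8.1	69.73	1.00	61.75	0.45	1.13	0.01	8
fruit	13S117_118	WT	59.08	0.66	62.18	0.64	0.95	0.09	8
anther	13S140	fs8.1	9.08	0.11	1.36	0.01	6.68	0.07	6
anther	13S140	WT	8.74	0.06	1.37	0.01	6.38	0.05	6
anther	13S117_118	fs8.1	9.44	0.09	1.44	0.02	6.59	0.09	6
anther	13S117_118	WT	8.81	0.11	1.39	0.02	6.32	0.07	6
petal	13S140	fs8.1	13.03	0.09	4.95	0.08	2.65	0.05	6
petal	13S140	WT	12.48	0.11	5.20	0.04	2.41	0.02	6
petal	13S117_118	fs8.1	15.60	0.25	6.03	0.21	2.62	0.08	6
petal	13S117_118	WT	13.34	0.20	5.85	0.20	2.31	0.07	6
sepal	13S140	fs8.1	14.74	0.42	1.56	0.02	9.43	0.19	6
sepal	13S140	WT	13.41	0.32	1.58	0.01	8.52	0.16	6
sepal	13S117_118	fs8.1	14.68	0.40	1.64	0.03	8.95	0.20	6
sepal	13S117_118	WT	11.90	0.39	1.67	0.03	7.14	0.27	6
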