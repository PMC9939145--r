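drug	pt	n	ror	ror_lo95	ror_hi95	prr	chi2	ic	ic025	ebgm	ebgm05
olaparib	Anemia	606	12.23	11.25	13.31	11.17	5616.08	3.47	3.32	11.09	10.20
olaparib	Myelodysplastic syndrome	184	49.51	42.66	57.46	48.11	8220.87	5.54	5.00	46.60	40.15
olaparib	Thrombocytopenia	128	4.26	3.58	5.08	4.20	312.19	2.07	1.76	4.19	3.51
olaparib	Acute myeloid leukemia	113	27.57	22.85	33.26	27.10	2789.80	4.73	4.15	26.62	22.06
olaparib	Pancytopenia	111	7.69	6.38	9.29	7.58	632.02	2.92	2.54	7.54	6.25
olaparib	Bone marrow failure	71	8.92	7.05	11.28	8.83	490.55	3.13	2.62	8.78	6.95
olaparib	Hematotoxicity	47	19.00	14.23	25.36	18.86	785.19	4.22	3.31	18.63	13.96
olaparib	Myelosuppression	46	13.71	10.25	18.35	13.62	533.28	3.76	2.96	13.50	10.09
olaparib	Metastases to lymph nodes	29	15.97	11.07	23.04	15.90	400.68	3.98	2.81	15.74	10.91
olaparib	Leukemia	18	6.16	3.88	9.80	6.15	77.32	2.62	1.51	6.13	3.85
olaparib	Cytopenia	14	4.07	2.41	6.88	4.06	32.27	2.02	0.88	4.06	2.40
olaparib	Hemolytic anemia	12	4.97	2.82	8.77	4.96	37.87	2.31	0.97	4.95	2.81
olaparib	Acute leukemia	12	29.76	16.79	52.73	29.71	326.19	4.86	2.25	29.13	16.44
olaparib	Blood disorder	10	4.47	2.40	8.33	4.47	26.86	2.16	0.71	4.46	2.40
olaparib	Anemia macrocytic	8	16.27	8.10	32.67	16.25	113.22	4.01	1.39	16.08	8.01
olaparib	Lymphangiosis carcinomatosa	7	22.11	10.48	46.65	22.08	138.80	4.44	1.31	21.77	10.31
olaparib	Bone marrow disorder	6	7.83	3.51	17.48	7.83	35.54	2.96	0.58	7.79	3.49
olaparib	Macrocytosis	5	15.65	6.48	37.79	15.64	67.78	3.95	0.62	15.48	6.41
olaparib	Aplasia pure red cell	5	6.78	2.82	16.34	6.78	24.52	2.76	0.23	6.75	2.80
olaparib	Myeloid leukemia	4	32.38	12.02	87.25	32.36	118.91	4.99	0.37	31.67	11.76
niraparib	Anemia	726	8.23	7.63	8.88	7.76	4269.84	2.94	2.82	7.69	7.13
niraparib	Thrombocytopenia	573	11.53	10.59	12.55	10.98	5155.95	3.44	3.29	10.85	9.97
niraparib	Lymphadenopathy	124	7.50	6.28	8.96	7.42	684.21	2.88	2.54	7.37	6.17
niraparib	Pancytopenia	118	4.70	3.92	5.64	4.66	338.56	2.22	1.89	4.64	3.87
niraparib	Petechiae	85	16.92	13.64	20.98	16.79	1238.25	4.04	3.47	16.48	13.29
niraparib	Bone marrow failure	68	4.92	3.87	6.24	4.89	209.64	2.28	1.83	4.87	3.83
niraparib	Myelodysplastic syndrome	45	6.67	4.97	8.94	6.64	214.15	2.72	2.09	6.60	4.92
niraparib	Acute myeloid leukemia	31	4.25	2.99	6.06	4.24	76.55	2.08	1.38	4.23	2.97
niraparib	Lymphoedema	30	8.76	6.11	12.56	8.74	203.63	3.11	2.22	8.66	6.04
niraparib	Platelet disorder	28	21.88	15.03	31.86	21.83	542.43	4.41	3.04	21.30	14.63
niraparib	Increased tendency to bruise	26	5.10	3.46	7.50	5.09	84.91	2.34	1.52	5.06	3.44
niraparib	Metastases to lymph nodes	24	7.62	5.09	11.39	7.60	136.40	2.91	1.93	7.54	5.04
niraparib	Bone marrow disorder	20	15.32	9.84	23.85	15.29	262.42	3.91	2.45	15.04	9.66
niraparib	Blood disorder	20	5.20	3.35	8.07	5.19	67.25	2.37	1.39	5.16	3.33
niraparib	Myelosuppression	17	3.42	2.12	5.51	3.42	28.97	1.77	0.80	3.41	2.12
niraparib	White blood cell disorder	11	7.33	4.05	13.28	7.33	59.60	2.86	1.26	7.27	4.02
niraparib	Transfusion reaction	9	26.86	13.83	52.18	26.84	216.97	4.70	1.76	26.04	13.41
niraparib	Red blood cell abnormality	8	16.65	8.27	33.53	16.64	115.29	4.03	1.39	16.33	8.11
niraparib	Abdominal lymphadenopathy	8	15.11	7.51	30.41	15.10	103.47	3.89	1.35	14.85	7.38
niraparib	Metastases to spleen	6	26.48	11.75	59.7	26.47	142.52	4.68	1.09	25.69	11.39
rucaparib	Anemia	438	8.93	8.10	9.84	8.36	2848.80	3.06	2.89	8.32	7.55
rucaparib	Thrombocytopenia	146	5.07	4.30	5.97	4.97	463.93	2.31	2.02	4.96	4.21
rucaparib	Bone marrow failure	36	4.66	3.35	6.46	4.63	102.43	2.21	1.55	4.62	3.33
rucaparib	Lymphadenopathy	31	3.32	2.33	4.73	3.31	49.88	1.72	1.06	3.30	2.32
rucaparib	Blood disorder	10	4.65	2.50	8.65	4.64	28.49	2.21	0.75	4.63	2.49
rucaparib	Lymphoedema	8	4.16	2.07	8.32	4.15	19.09	2.05	0.43	4.14	2.07
rucaparib	Bone marrow disorder	8	10.87	5.42	21.80	10.86	71.09	3.43	1.18	10.79	5.38
talazoparib	Anemia	61	17.93	13.69	23.48	15.66	843.98	3.97	3.25	15.65	11.95
talazoparib	Thrombocytopenia	36	17.85	12.70	25.09	16.52	527.04	4.05	3.00	16.51	11.74
talazoparib	Pancytopenia	25	25.17	16.82	37.68	23.85	547.89	4.57	3.02	23.82	15.91
talazoparib	Neutropenia	19	7.53	4.76	11.92	7.26	103.05	2.86	1.72	7.25	4.58
talazoparib	Febrile neutropenia	16	12.76	7.74	21.01	12.34	167.16	3.62	2.07	12.34	7.49
talazoparib	Leukopenia	8	8.11	4.03	16.32	7.98	48.96	3.00	0.97	7.98	3.97
talazoparib	Hematotoxicity	8	45.34	22.52	91.29	44.56	340.07	5.47	1.73	44.47	22.08
talazoparib	Myelodysplastic syndrome	6	21.60	9.65	48.35	21.32	116.18	4.41	1.04	21.30	9.52
talazoparib	Cytopenia	4	16.39	6.12	43.89	16.26	57.27	4.02	0.23	16.25	6.07
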