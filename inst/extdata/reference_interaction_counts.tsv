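roi	group	is_group_row	n_total	pos_w_n	pos_w_pct	pos_s_n	pos_s_pct	pos_u_n	pos_u_pct	neg_w_n	neg_w_pct	neg_s_n	neg_s_pct	neg_u_n	neg_u_pct	inconsistent_cells
HGPM	HGPM	TRUE	44	20	45.5	8	18.2	0	0	0	0	0	0	0	0	-
STP	STP	TRUE	64	19	29.7	11	17.2	0	0	0	0	3	4.69	0	0	-
HGAL	STP	FALSE	25	7	28	5	20	0	0	0	0	1	4	0	0	-
PT	STP	FALSE	21	11	52.4	5	23.8	0	0	0	0	0	0	0	0	-
PP	STP	FALSE	18	1	5.56	1	5.56	0	0	0	0	2	11.1	0	0	-
STG	STG	TRUE	109	46	42.2	27	24.8	4	3.67	1	0.972	2	1.83	0	0	neg_w
Posterior STG	STG	FALSE	72	37	51.4	19	26.4	2	2.78	1	1.39	2	3.78	0	0	neg_s
Middle STG	STG	FALSE	37	9	24.3	8	21.6	2	5.41	0	0	0	0	0	0	-
Auditory-related	Auditory-related	TRUE	364	30	8.24	13	3.57	1	0.275	20	5.49	7	1.92	5	1.37	-
Anterior STG	Auditory-related	FALSE	17	1	5.88	0	0	0	0	1	5.88	0	0	0	0	-
STSU	Auditory-related	FALSE	12	4	33.3	0	0	0	0	3	25	0	0	0	0	-
STSL	Auditory-related	FALSE	19	4	21.1	1	5.26	0	0	1	5.26	0	0	0	0	-
MTG	Auditory-related	FALSE	187	9	4.81	4	2.14	1	0.535	9	4.81	3	1.6	2	1.07	-
SMG	Auditory-related	FALSE	65	6	9.23	4	6.15	0	0	3	4.62	3	4.62	1	1.54	-
AG	Auditory-related	FALSE	56	5	8.93	3	5.36	0	0	3	5.36	1	1.79	2	3.57	-
Prefrontal	Prefrontal	TRUE	251	5	1.99	2	0.797	1	0.398	14	5.58	3	1.2	3	1.2	-
IFG	Prefrontal	FALSE	55	2	3.64	0	0	0	0	6	10.9	2	3.63	1	1.82	neg_s
MFG	Prefrontal	FALSE	80	1	1.25	1	1.25	0	0	4	5	1	1.25	2	2.5	-
SFG	Prefrontal	FALSE	15	0	0	0	0	0	0	0	0	0	0	0	0	-
OG	Prefrontal	FALSE	76	1	1.32	1	1.32	1	1.32	3	3.95	0	0	0	0	-
TFG	Prefrontal	FALSE	19	0	0	0	0	0	0	0	0	0	0	0	0	-
Other	Other	TRUE	339	21	6.19	3	0.885	3	0.885	7	2.06	19	5.6	2	0.59	-
Inferior temporal g.	Other	FALSE	62	3	4.84	1	1.61	0	0	0	0	5	8.06	1	1.61	-
Temporal pole	Other	FALSE	58	2	3.45	1	1.72	0	0	0	0	2	3.45	0	0	-
Precentral g.	Other	FALSE	44	8	18.2	0	0	0	0	1	2.27	3	6.82	0	0	-
Postcentral g.	Other	FALSE	30	1	3.33	0	0	0	0	1	3.33	2	6.67	0	0	-
Parahippocampal g.	Other	FALSE	21	0	0	0	0	0	0	1	4.76	1	4.76	0	0	-
Fusiform g.	Other	FALSE	20	1	5	0	0	1	5	0	0	1	5	0	0	-
G. rectus	Other	FALSE	20	0	0	0	0	0	0	0	0	3	15	0	0	-
Premotor cortex	Other	FALSE	14	1	7.14	0	0	1	7.14	0	0	0	0	1	7.14	-
Hippocampus	Other	FALSE	13	0	0	0	0	0	0	1	7.69	0	0	0	0	-
Amygdala	Other	FALSE	12	0	0	0	0	0	0	0	0	0	0	0	0	-
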