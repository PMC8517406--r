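subject	age	sex	hgpm	stp	stg	auditory_related	prefrontal	other	total
R369	30	M	8	15	17	79	39	54	212
L372	34	M	6	12	25	51	34	49	177
R376	48	F	7	10	18	76	30	52	193
R394	24	M	8	2	0	6	2	7	25
R399	22	F	3	6	21	46	47	60	183
L400	59	F	4	7	3	25	54	65	158
R413	21	M	8	12	25	81	45	52	223
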