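analyte	row_type	bovine	caprine	ovine	sem_milk	q25	q75	sem_location	p_milk	p_location
Ile	component	33.2	45.7	49.1	5.2	37.4	47.9	3.2	NS	***
Leu	component	30.2	40.9	51.5	5.1	35.5	46.3	3.2	*	**
Val	component	28.4	40.5	44.4	5.4	32.3	43.2	3.3	NS	***
BCAA	total	29.5	41.1	46.2	5.3	35.1	42.8	3.3	NS	**
His	component	16.2	29.8	49.1	5.8	25.3	38.0	3.7	*	**
Lys	component	-20.1	1.4	33.4	8.3	-4.0	13.9	5.2	**	**
Met	component	9.3	14.7	40.3	6.8	14.7	28.2	4.3	*	**
Phe	component	24.2	36.9	45.5	5.5	29.6	41.5	3.5	NS	**
Thr	component	24.5	36.7	48.1	5.0	30.3	42.6	3.1	*	***
EAA	total	20.3	33.4	42.8	5.8	27.8	36.5	3.6	NS	**
Ala	component	28.2	47.3	55.6	3.9	38.3	49.1	2.5	**	***
Arg	component	9.9	25.6	41.7	4.8	18.1	33.4	3.2	**	***
Asp	component	19.5	37.9	51.6	5.5	30.6	42.1	3.6	**	***
Glu	component	24.7	36.5	47.7	5.8	30.9	41.7	3.6	*	**
Ser	component	20.5	33.8	46.2	5.5	27.2	39.8	3.5	*	***
Tyr	component	16.3	33.8	17.4	7.4	15.4	29.5	4.6	NS	**
NEAA	total	20.6	37.9	48.0	5.7	28.9	37.3	3.5	*	**
LNAA	total	19.2	37.4	32.7	6.4	23.6	32.6	4.0	NS	**
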