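analyte	row_type	bovine	bovine_sem	caprine	caprine_sem	ovine	ovine_sem
Ile	component	0.61	0.06	0.42	0.05	0.37	0.05
Leu	component	0.64	0.06	0.46	0.05	0.35	0.05
Val	component	0.66	0.06	0.47	0.05	0.41	0.06
Total BCAA	total	0.64	0.06	0.45	0.05	0.37	0.05
His	component	0.77	0.07	0.55	0.06	0.36	0.05
Lys	component	1.11	0.12	0.78	0.08	0.47	0.07
Met	component	0.85	0.08	0.68	0.08	0.44	0.06
Phe	component	0.69	0.06	0.49	0.05	0.39	0.05
Thr	component	0.64	0.07	0.47	0.05	0.35	0.05
Total EAA	total	0.72	0.07	0.51	0.06	0.39	0.05
Ala	component	0.60	0.06	0.37	0.04	0.30	0.04
Arg	component	0.77	0.07	0.53	0.05	0.38	0.05
Asp	component	0.71	0.07	0.48	0.05	0.34	0.05
Glu	component	0.70	0.07	0.52	0.06	0.39	0.06
Ser	component	0.71	0.07	0.50	0.06	0.37	0.05
Tyr	component	0.77	0.07	0.51	0.06	0.59	0.08
Total NEAA	total	0.71	0.07	0.49	0.05	0.40	0.05
Total LNAA	total	0.67	0.06	0.47	0.05	0.42	0.06
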