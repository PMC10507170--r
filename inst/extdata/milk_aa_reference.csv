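species,analyte,row_type,mg_per_g_protein,sem
bovine,Isoleucine,component,30.1,0.61
bovine,Leucine,component,52.4,1.05
bovine,Valine,component,34.6,0.73
bovine,Total BCAA,total,117.0,2.40
bovine,Histidine,component,12.2,0.26
bovine,Lysine,component,23.8,0.54
bovine,Methionine,component,12.0,0.17
bovine,Phenylalanine,component,26.2,0.55
bovine,Threonine,component,22.0,0.55
bovine,Tryptophan,component,14.4,0.27
bovine,Total EAA,total,227.6,4.58
bovine,Alanine,component,17.0,0.40
bovine,Arginine,component,17.8,0.40
bovine,Asparagine,component,36.6,1.42
bovine,Cysteine,component,6.5,0.14
bovine,Glutamine,component,127.3,3.34
bovine,Serine,component,27.9,0.71
bovine,Tyrosine,component,25.5,0.68
bovine,Total NEAA,total,268.0,7.04
bovine,Total LNAA,total,183.1,3.77
caprine,Isoleucine,component,31.3,0.20
caprine,Leucine,component,56.5,0.25
caprine,Valine,component,41.6,0.34
caprine,Total BCAA,total,129.4,0.78
caprine,Histidine,component,13.2,0.11
caprine,Lysine,component,25.2,0.14
caprine,Methionine,component,11.7,0.31
caprine,Phenylalanine,component,28.7,0.21
caprine,Threonine,component,27.7,0.29
caprine,Tryptophan,component,14.8,0.07
caprine,Total EAA,total,250.7,1.37
caprine,Alanine,component,16.8,0.14
caprine,Arginine,component,16.5,0.07
caprine,Asparagine,component,37.1,0.81
caprine,Cysteine,component,7.5,0.44
caprine,Glutamine,component,132.7,1.26
caprine,Serine,component,27.8,0.23
caprine,Tyrosine,component,23.0,0.12
caprine,Total NEAA,total,270.9,2.56
caprine,Total LNAA,total,195.9,1.04
ovine,Isoleucine,component,37.0,0.40
ovine,Leucine,component,74.1,0.95
ovine,Valine,component,42.9,0.39
ovine,Total BCAA,total,154.0,1.73
ovine,Histidine,component,18.9,0.25
ovine,Lysine,component,42.1,0.16
ovine,Methionine,component,18.2,0.20
ovine,Phenylalanine,component,34.5,0.55
ovine,Threonine,component,31.7,0.35
ovine,Tryptophan,component,15.0,0.16
ovine,Total EAA,total,314.4,2.85
ovine,Alanine,component,27.7,0.37
ovine,Arginine,component,25.6,0.17
ovine,Asparagine,component,58.3,0.63
ovine,Cysteine,component,7.1,0.33
ovine,Glutamine,component,172.4,1.93
ovine,Serine,component,39.4,0.39
ovine,Tyrosine,component,35.5,0.17
ovine,Total NEAA,total,383.7,3.04
ovine,Total LNAA,total,240.9,2.11
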