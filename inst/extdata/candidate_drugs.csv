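drug,biomarker,regulation_ability,sensitivity,lc50
CCT-018159,STAT3,-0.68150,0.068573,5.187
Mofezolac,STAT3,-0.34939,0.027005,5.684
Eliprodil,STAT3,-2.14303,-0.00262,5.23
Butein,STAT3,-1.46898,-0.05445,5.776
LY-303511,STAT3,-0.57210,-0.44921,5.075
Limonin,CEBPB,-3.138645411,-0.10563,6.726
Mofezolac,CEBPB,-0.427841723,0.027005,5.684
Betulinic-acid,CEBPB,-0.934850574,-0.10344,6.712
Tangeritin,CEBPB,-0.260343373,-0.00037,5.488
SB-415286,CEBPB,-0.291000009,0.011518,6.282
Naringin,ERK1/2,-0.12728,0.132488,6.921
Mofezolac,ERK1/2,-0.4780038,0.027005,5.684
Betulinic-acid,ERK1/2,-0.65759182,-0.10344,6.712
Quercetin,ERK1/2,-0.297982544,-0.03326,5.222
BIBU-1361,ERK1/2,-0.908186227,0.155512,6.201
Naringin,NF-kB,-0.12728,0.132488,6.921
Mofezolac,NF-kB,-1.00891,0.027005,5.684
Butein,NF-kB,-1.46898,-0.05445,5.776
Ro-04-5595,NF-kB,-0.2619,-0.00387,5.443
Flavoxate,NF-kB,-0.75315,0.107694,5.861
Naringin,FOXO1,0.579085,0.132488,6.921
Mofezolac,FOXO1,0.748792,0.027005,5.684
Betulinic-acid,FOXO1,0.756684,-0.10344,6.712
Penfluridol,FOXO1,0.892637,0.144082,6.202
Dexamethasone,FOXO1,0.763925,0.122088,5.128
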