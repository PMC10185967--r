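# Reference disease counts and support-sum node strengths among adults aged
# 65+ in a national Korean health survey, by sex and HRQoL group (poor:
# EQ-5D index <= 0.721; good: index = 1.00; normal: in between).
# Stratum sizes: male good/normal/poor = 3098/1907/457;
#                female good/normal/poor = 2579/3270/1346.
sex,hrqol,disease,count,node_strength
male,good,angina_pectoris,155,0.09
male,good,arthritis,245,0.12
male,good,asthma,79,0.04
male,good,cancer,291,0.12
male,good,ckd,298,0.18
male,good,depression,40,0.02
male,good,diabetes,586,0.31
male,good,hyperlipidemia,558,0.33
male,good,hypertension,1440,0.55
male,good,liver_disease,77,0.04
male,good,myocardial_infarction,103,0.07
male,good,renal_failure,19,0.01
male,good,stroke,126,0.08
male,good,thyroid,46,0.02
male,good,tuberculosis,289,0.12
male,normal,angina_pectoris,131,0.16
male,normal,arthritis,359,0.32
male,normal,asthma,100,0.10
male,normal,cancer,180,0.17
male,normal,ckd,263,0.30
male,normal,depression,75,0.08
male,normal,diabetes,429,0.47
male,normal,hyperlipidemia,357,0.42
male,normal,hypertension,1027,0.81
male,normal,liver_disease,50,0.05
male,normal,myocardial_infarction,79,0.10
male,normal,renal_failure,16,0.03
male,normal,stroke,164,0.18
male,normal,thyroid,27,0.03
male,normal,tuberculosis,196,0.18
male,poor,angina_pectoris,41,0.23
male,poor,arthritis,131,0.55
male,poor,asthma,41,0.22
male,poor,cancer,46,0.19
male,poor,ckd,77,0.42
male,poor,depression,36,0.23
male,poor,diabetes,139,0.70
male,poor,hyperlipidemia,88,0.54
male,poor,hypertension,255,1.11
male,poor,liver_disease,20,0.14
male,poor,myocardial_infarction,32,0.20
male,poor,renal_failure,7,0.05
male,poor,stroke,98,0.48
male,poor,thyroid,4,0.02
male,poor,tuberculosis,50,0.23
female,good,angina_pectoris,97,0.10
female,good,arthritis,809,0.51
female,good,asthma,108,0.09
female,good,cancer,128,0.09
female,good,ckd,200,0.17
female,good,depression,143,0.12
female,good,diabetes,467,0.39
female,good,hyperlipidemia,791,0.56
female,good,hypertension,1390,0.79
female,good,liver_disease,39,0.04
female,good,myocardial_infarction,30,0.04
female,good,renal_failure,10,0.01
female,good,stroke,96,0.08
female,good,thyroid,145,0.12
female,good,tuberculosis,122,0.08
female,normal,angina_pectoris,176,0.15
female,normal,arthritis,1661,0.90
female,normal,asthma,189,0.14
female,normal,cancer,178,0.11
female,normal,ckd,313,0.25
female,normal,depression,300,0.22
female,normal,diabetes,684,0.49
female,normal,hyperlipidemia,1106,0.76
female,normal,hypertension,1938,1.07
female,normal,liver_disease,58,0.04
female,normal,myocardial_infarction,56,0.05
female,normal,renal_failure,19,0.02
female,normal,stroke,148,0.12
female,normal,thyroid,181,0.13
female,normal,tuberculosis,150,0.11
female,poor,angina_pectoris,103,0.25
female,poor,arthritis,845,1.27
female,poor,asthma,129,0.26
female,poor,cancer,73,0.14
female,poor,ckd,174,0.39
female,poor,depression,176,0.37
female,poor,diabetes,324,0.68
female,poor,hyperlipidemia,393,0.82
female,poor,hypertension,842,1.36
female,poor,liver_disease,25,0.05
female,poor,myocardial_infarction,43,0.12
female,poor,renal_failure,16,0.04
female,poor,stroke,132,0.29
female,poor,thyroid,83,0.18
female,poor,tuberculosis,66,0.13
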