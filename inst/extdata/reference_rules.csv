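# Reference top-20 pairwise disease association rules (ordered by support)
# in the poor-HRQoL group of a national Korean health survey of adults 65+,
# by sex. Percentages are printed to one decimal (half-up); lift to one
# decimal. Stratum sizes: male n = 457, female n = 1346.
sex,antecedent,consequent,support_pct,confidence_pct,lift
male,hypertension,diabetes,20.8,37.3,1.2
male,diabetes,hypertension,20.8,68.3,1.2
male,hypertension,arthritis,15.8,28.2,1.0
male,arthritis,hypertension,15.8,55.0,1.0
male,hypertension,hyperlipidemia,15.1,27.1,1.4
male,hyperlipidemia,hypertension,15.1,78.4,1.4
male,hypertension,stroke,13.8,24.7,1.2
male,stroke,hypertension,13.8,64.3,1.2
male,hypertension,ckd,12.3,22.0,1.3
male,ckd,hypertension,12.3,72.7,1.3
male,stroke,diabetes,9.4,43.9,1.4
male,diabetes,stroke,9.4,30.9,1.4
male,hyperlipidemia,diabetes,8.1,42.0,1.4
male,diabetes,hyperlipidemia,8.1,26.6,1.4
male,arthritis,diabetes,6.3,22.1,0.7
male,diabetes,arthritis,6.3,20.9,0.7
male,diabetes,ckd,6.3,20.9,1.2
male,ckd,diabetes,6.3,37.7,1.2
male,hypertension,angina_pectoris,5.7,10.2,1.1
male,angina_pectoris,hypertension,5.7,63.4,1.1
female,hypertension,arthritis,41.6,66.5,1.1
female,arthritis,hypertension,41.6,66.3,1.1
female,hypertension,hyperlipidemia,22.5,36.0,1.2
female,hyperlipidemia,hypertension,22.5,77.1,1.2
female,hyperlipidemia,arthritis,20.1,68.7,1.1
female,arthritis,hyperlipidemia,20.1,32.0,1.1
female,hypertension,diabetes,19.1,30.5,1.3
female,diabetes,hypertension,19.1,79.3,1.3
female,arthritis,diabetes,15.8,25.1,1.0
female,diabetes,arthritis,15.8,65.4,1.0
female,hyperlipidemia,diabetes,10.8,36.9,1.5
female,diabetes,hyperlipidemia,10.8,44.8,1.5
female,hypertension,ckd,10.2,16.3,1.3
female,ckd,hypertension,10.2,78.7,1.3
female,arthritis,depression,8.8,14.0,1.1
female,depression,arthritis,8.8,67.0,1.1
female,hypertension,depression,8.2,13.2,1.0
female,depression,hypertension,8.2,63.1,1.0
female,hypertension,stroke,7.8,12.5,1.3
female,stroke,hypertension,7.8,79.5,1.3
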