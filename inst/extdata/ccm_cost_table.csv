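country,stratum,u5mr,antibiotic_cost,nonantibiotic_cost,total_cost
Nigeria,Overall,189.00,0.27,2.52,2.79
Nigeria,Q1,87.00,0.27,1.43,1.70
Nigeria,Q2,129.00,0.27,1.87,2.14
Nigeria,Q3,165.00,0.27,2.26,2.53
Nigeria,Q4,212.00,0.27,2.76,3.03
Nigeria,Q5,219.00,0.27,2.84,3.11
Egypt,Overall,36.00,0.27,0.88,1.15
Egypt,Q1,18.90,0.27,0.70,0.97
Egypt,Q2,27.20,0.27,0.79,1.06
Egypt,Q3,32.20,0.27,0.84,1.11
Egypt,Q4,36.10,0.27,0.88,1.15
Egypt,Q5,49.00,0.27,1.02,1.29
Bangladesh,Overall,61.00,0.27,1.15,1.42
Bangladesh,Q1,43.00,0.27,0.95,1.22
Bangladesh,Q2,62.00,0.27,1.16,1.43
Bangladesh,Q3,83.00,0.27,1.38,1.65
Bangladesh,Q4,85.00,0.27,1.40,1.67
Bangladesh,Q5,86.00,0.27,1.41,1.68
Cambodia,Overall,54.00,0.27,1.07,1.34
Cambodia,Q1,30.00,0.27,0.82,1.09
Cambodia,Q2,49.00,0.27,1.02,1.29
Cambodia,Q3,68.00,0.27,1.22,1.49
Cambodia,Q4,83.00,0.27,1.38,1.65
Cambodia,Q5,90.00,0.27,1.46,1.73
Peru,Overall,27.00,0.27,0.78,1.05
Peru,Q1,9.00,0.27,0.59,0.86
Peru,Q2,24.00,0.27,0.75,1.02
Peru,Q3,24.00,0.27,0.75,1.02
Peru,Q4,33.00,0.27,0.85,1.12
Peru,Q5,59.00,0.27,1.13,1.40
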