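sex,age_group,n,standard,mean_diff,sd
male,4.00-4.99,7,french_canadian,0.75,0.18
male,5.00-5.99,12,french_canadian,0.82,0.78
male,6.00-6.99,26,french_canadian,1.04,0.35
male,7.00-7.99,28,french_canadian,0.66,0.42
male,8.00-8.99,26,french_canadian,0.69,0.98
male,9.00-9.99,30,french_canadian,0.97,0.84
male,10.00-10.99,30,french_canadian,1.21,0.56
male,11.00-11.99,16,french_canadian,0.17,1.05
male,12.00-12.99,30,french_canadian,0.69,1.18
male,13.00-13.99,12,french_canadian,-0.12,0.69
male,4.00-4.99,7,belgian,-1.26,0.53
male,5.00-5.99,12,belgian,0.11,1.67
male,6.00-6.99,26,belgian,1.57,0.96
male,7.00-7.99,28,belgian,2.11,1.01
male,8.00-8.99,26,belgian,2.81,1.33
male,9.00-9.99,30,belgian,3.23,0.82
male,10.00-10.99,30,belgian,3.05,0.48
male,11.00-11.99,16,belgian,2.14,0.65
male,12.00-12.99,30,belgian,1.91,0.53
male,13.00-13.99,12,belgian,1.2,0.86
male,4.00-4.99,7,kuwaiti,0.03,0.17
male,5.00-5.99,12,kuwaiti,0.04,0.79
male,6.00-6.99,26,kuwaiti,0.51,0.7
male,7.00-7.99,28,kuwaiti,0.6,0.69
male,8.00-8.99,26,kuwaiti,0.85,0.92
male,9.00-9.99,30,kuwaiti,0.83,0.57
male,10.00-10.99,30,kuwaiti,0.6,0.48
male,11.00-11.99,16,kuwaiti,-0.39,0.62
male,12.00-12.99,30,kuwaiti,-0.2,1.15
male,13.00-13.99,12,kuwaiti,-1.51,0.63
male,7.00-7.99,28,alemran_saudi,1.68,0
male,8.00-8.99,26,alemran_saudi,1.22,0.77
male,9.00-9.99,30,alemran_saudi,0.95,0.68
male,10.00-10.99,30,alemran_saudi,0.8,0.43
male,11.00-11.99,16,alemran_saudi,-0.19,0.67
male,12.00-12.99,30,alemran_saudi,-0.19,0.88
male,13.00-13.99,12,alemran_saudi,-1.22,0.41
female,4.00-4.99,9,french_canadian,0.9,0.72
female,5.00-5.99,20,french_canadian,1.26,0.66
female,6.00-6.99,22,french_canadian,1.13,0.45
female,7.00-7.99,40,french_canadian,0.98,0.65
female,8.00-8.99,38,french_canadian,0.42,0.69
female,9.00-9.99,24,french_canadian,0.36,0.83
female,10.00-10.99,24,french_canadian,1.05,0.7
female,11.00-11.99,6,french_canadian,0.53,0.42
female,12.00-12.99,12,french_canadian,0.74,1.05
female,13.00-13.99,10,french_canadian,1.08,1.06
female,4.00-4.99,9,belgian,-0.36,1.41
female,5.00-5.99,20,belgian,1.38,1.36
female,6.00-6.99,22,belgian,1.96,0.85
female,7.00-7.99,40,belgian,2.82,1.22
female,8.00-8.99,38,belgian,2.73,0.83
female,9.00-9.99,24,belgian,2.95,1.02
female,10.00-10.99,24,belgian,3.28,0.68
female,11.00-11.99,6,belgian,2.68,0.04
female,12.00-12.99,12,belgian,2.03,0.47
female,13.00-13.99,10,belgian,1.79,0.41
female,4.00-4.99,9,kuwaiti,0.62,0.52
female,5.00-5.99,20,kuwaiti,0.95,0.69
female,6.00-6.99,22,kuwaiti,0.92,0.62
female,7.00-7.99,40,kuwaiti,1.24,0.82
female,8.00-8.99,38,kuwaiti,0.76,0.53
female,9.00-9.99,24,kuwaiti,0.56,0.67
female,10.00-10.99,24,kuwaiti,0.5,0.9
female,11.00-11.99,6,kuwaiti,0.15,0.34
female,12.00-12.99,12,kuwaiti,0.25,1.35
female,13.00-13.99,10,kuwaiti,-0.15,1.34
female,7.00-7.99,40,alemran_saudi,1.51,0.57
female,8.00-8.99,38,alemran_saudi,0.9,0.57
female,9.00-9.99,24,alemran_saudi,0.6,0.65
female,10.00-10.99,24,alemran_saudi,0.76,0.56
female,11.00-11.99,6,alemran_saudi,0.17,0.27
female,12.00-12.99,12,alemran_saudi,-0.09,0.98
female,13.00-13.99,10,alemran_saudi,0.88,1.43
male,4.00-4.99,7,table1_da_ca,0.75,0.18
male,5.00-5.99,12,table1_da_ca,0.83,0.79
male,6.00-6.99,26,table1_da_ca,1.04,0.35
male,7.00-7.99,28,table1_da_ca,0.66,0.42
male,8.00-8.99,26,table1_da_ca,0.7,0.98
male,9.00-9.99,30,table1_da_ca,0.97,0.85
male,10.00-10.99,30,table1_da_ca,1.21,0.56
male,11.00-11.99,16,table1_da_ca,0.17,1.05
male,12.00-12.99,30,table1_da_ca,0.69,1.18
male,13.00-13.99,12,table1_da_ca,-0.12,0.69
female,4.00-4.99,9,table1_da_ca,0.9,0.72
female,5.00-5.99,20,table1_da_ca,1.26,0.66
female,6.00-6.99,22,table1_da_ca,1.13,0.45
female,7.00-7.99,40,table1_da_ca,0.98,0.69
female,8.00-8.99,38,table1_da_ca,0.42,0.69
female,9.00-9.99,24,table1_da_ca,0.36,0.83
female,10.00-10.99,24,table1_da_ca,1.05,0.7
female,11.00-11.99,6,table1_da_ca,0.53,0.42
female,12.00-12.99,12,table1_da_ca,0.74,1.05
female,13.00-13.99,10,table1_da_ca,1.08,1.06
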