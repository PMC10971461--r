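subject,group,ofr_c,sd_c,sem_c,ofr_ac,sd_ac,sem_ac,p_comparison
HC1,control,0.360,0.253,0.073,0.230,0.118,0.038,0.048
HC2,control,0.394,0.137,0.045,0.167,0.230,0.064,0.010
HC3,control,0.700,0.241,0.073,0.450,0.209,0.065,0.016
HC4,control,0.534,0.212,0.057,0.356,0.161,0.054,0.014
HC5,control,0.420,0.186,0.056,0.145,0.250,0.065,<0.001
HC6,control,0.280,0.197,0.054,0.111,0.301,0.084,0.088
P1,patient,0.309,0.158,0.038,0.418,0.182,0.040,0.092
P2,patient,0.547,0.328,0.088,0.508,0.308,0.089,0.738
P3,patient,0.360,0.157,0.049,0.354,0.183,0.059,0.936
P4,patient,0.207,0.232,0.065,0.258,0.160,0.043,0.554
P5,patient,0.435,0.255,0.079,0.566,0.167,0.069,0.184
P6,patient,0.362,0.202,0.049,0.393,0.157,0.042,0.632
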