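subject,group,condition,mean_up,sd_up,n_up,mean_dw,sd_dw,n_dw,p_t,p_np
HC1,control,correlated,0.227,0.234,12,-0.133,0.096,13,<0.001,<0.001
HC2,control,correlated,0.220,0.088,6,-0.174,0.105,13,<0.001,<0.001
HC3,control,correlated,0.424,0.157,10,-0.277,0.183,11,<0.001,<0.001
HC4,control,correlated,0.293,0.101,13,-0.242,0.186,15,<0.001,<0.001
HC5,control,correlated,0.216,0.131,12,-0.204,0.132,11,<0.001,<0.001
HC6,control,correlated,0.157,0.125,16,-0.123,0.152,11,<0.001,<0.001
P1,patient,correlated,0.192,0.119,18,-0.116,0.104,18,<0.001,<0.001
P2,patient,correlated,0.124,0.177,14,-0.423,0.276,14,<0.001,<0.001
P3,patient,correlated,0.187,0.104,12,-0.173,0.117,9,<0.001,<0.001
P4,patient,correlated,0.090,0.184,12,-0.117,0.141,16,0.003,0.003
P5,patient,correlated,0.278,0.136,11,-0.157,0.216,10,<0.001,0.001
P6,patient,correlated,0.126,0.101,14,-0.236,0.176,17,<0.001,<0.001
HC1,control,anticorrelated,0.102,0.111,9,-0.127,0.041,12,<0.001,<0.001
HC2,control,anticorrelated,0.168,0.175,11,0.001,0.149,12,0.028,0.006
HC3,control,anticorrelated,0.158,0.120,8,-0.291,0.171,12,<0.001,<0.001
HC4,control,anticorrelated,0.232,0.154,10,-0.124,0.049,6,<0.001,<0.001
HC5,control,anticorrelated,0.100,0.165,15,-0.045,0.188,14,0.042,0.017
HC6,control,anticorrelated,0.158,0.086,16,0.047,0.289,12,0.172,0.024
P1,patient,anticorrelated,0.163,0.115,17,-0.255,0.141,22,<0.001,<0.001
P2,patient,anticorrelated,0.155,0.256,12,-0.353,0.172,13,<0.001,<0.001
P3,patient,anticorrelated,0.143,0.132,9,-0.211,0.127,10,<0.001,0.001
P4,patient,anticorrelated,0.131,0.132,13,-0.127,0.091,15,<0.001,<0.001
P5,patient,anticorrelated,0.288,0.138,6,-0.278,0.094,7,<0.001,0.001
P6,patient,anticorrelated,0.187,0.104,17,-0.206,0.117,14,<0.001,<0.001
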