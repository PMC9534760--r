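population,trait_name,acclimation_c,n,mean,se
Nueva,CTmax,6,11,36.06,0.13
Nueva,CTmax,13,12,36.37,0.08
Nueva,CTmax,20,16,36.84,0.08
Nueva,CTmax,27,16,38.21,0.05
Cortegueros,CTmax,6,16,35.91,0.10
Cortegueros,CTmax,13,16,36.16,0.09
Cortegueros,CTmax,20,16,36.76,0.09
Cortegueros,CTmax,27,16,38.11,0.11
Pandecarmen,CTmax,6,17,35.64,0.07
Pandecarmen,CTmax,13,17,36.02,0.09
Pandecarmen,CTmax,20,16,37.04,0.11
Pandecarmen,CTmax,27,17,38.30,0.09
Aliva,CTmax,6,15,36.21,0.14
Aliva,CTmax,13,14,36.65,0.08
Aliva,CTmax,20,14,37.46,0.11
Aliva,CTmax,27,12,38.32,0.11
Llagusecu,CTmax,6,14,36.26,0.10
Llagusecu,CTmax,13,14,36.53,0.10
Llagusecu,CTmax,20,14,37.03,0.12
Llagusecu,CTmax,27,14,38.43,0.11
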