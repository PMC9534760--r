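population,elevation_m,ctmax_n,ctmax_mean,ctmax_se,ctmin_n,ctmin_mean,ctmin_se,TMAX,tmax,TMIN,tmin,SR,sr,dr,WT,wt,CT,ct
Llagusecu,1835,14,37.0,0.1,14,-1.9,0.1,14.1,29.7,1.4,0.5,5.4,29.2,5.5,22.9,7.3,3.3,2.4
Senales,1635,14,36.8,0.1,16,-1.8,0.1,15.6,22.6,-1.2,4,7.0,18.6,4.9,21.2,14.2,0.6,5.8
Aliva,1418,14,37.5,0.1,16,-1.9,0.1,16.3,24.5,-0.5,4.3,6.3,20.2,6.5,21.2,13.0,1.4,6.2
Pandebano,1219,16,36.7,0.1,16,-1.9,0.1,15.4,28.9,-0.8,0.6,6.9,28.3,7.8,21.3,7.8,1.1,2.5
Pandecarmen,1106,16,37.0,0.1,16,-1.8,0.1,16.8,33,-0.3,0.2,7.5,34.6,13.1,20.2,4.0,1.5,2.0
Fana,950,16,36.5,0.1,16,-1.3,0.1,17.2,29.3,-0.2,1.5,7.4,27.8,8.9,19.3,7.2,1.1,2.8
Cortegueros,650,16,36.8,0.1,12,-1.6,0.1,18.9,28.4,1.8,1,7.5,27.4,6.2,17.9,8.4,3.3,2.6
Viango,480,16,37.1,0.1,15,-2.1,0.2,19.3,25.6,1.9,2.4,7.0,23.2,5.0,17.8,11.5,4,4.5
Color,380,16,36.9,0.1,16,-2.3,0.1,19.1,22.5,3,3.8,6.7,18.7,1.0,17.8,14.4,5.3,6.1
Nueva,140,16,36.8,0.1,13,-1.9,0.1,21.1,15.7,5,6.4,7.1,9.3,1.7,15.7,21.1,6.9,8.3
Puron,36,16,36.4,0.1,16,-0.9,0.1,21.7,11.4,4.7,9.9,7.6,1.5,0.4,14.7,25.0,5.6,10.8
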