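animal_id,median_h,mean_h,sse
B445a,34,40.1,0.00079
B445b,36,44.8,0.0039
B481,36,41.9,3.4e-23
B687,22,34.2,0.0039
B857a,24,30.2,0.0025
B857b,26,29.3,0.0041
R153a,26,31.4,0.016
R153b,26,26.0,0.044
R401,18,29.8,0.03
R632,26,34.4,0.23
R634,14,17.6,0.72
R705,22,24.3,0.16
R797,22,29.9,0.055
R798,22,26.1,0.104
R890,22,24.6,0.19
Y044a,26,34.3,0.017
Y044b,30,34.0,0.0028
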