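animal_id,sse_lasso,sse_mc,sse_inverse_gaussian,sse_gaussian
B445a,1.04,1.20,1.21,0.88
B857a,8.02,12.20,5.39,19.50
B857b,1.19,1.59,0.27,0.93
R632,57.45,64.48,46.38,48.52
R634,13.07,11.98,13.23,24.23
R797,1.92,1.48,2.89,8.11
R798,2.49,1.62,3.96,7.21
Y044b,0.87,0.58,1.47,1.83
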