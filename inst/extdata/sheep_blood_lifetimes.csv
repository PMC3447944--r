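animal_id,mean_lifetime_h
B445a,6.4
B445b,5.3
B481,9.7
B687,7.5
B857a,20.6
B857b,10.5
R153a,7.1
R153b,10.3
R401,6.4
R632,7.2
R634,10.3
R705,6.4
R797,7.2
R798,10.3
R890,7.3
Y044a,8.0
Y044b,6.3
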