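month,year_set,alpha,gpp_ref
5,2018,0.059,21.19
5,2019,0.050,15.45
5,others,0.061,18.80
6,2018,0.088,26.78
6,2019,0.056,19.19
6,others,0.089,26.32
7,2018,0.078,19.07
7,2019,0.067,18.51
7,others,0.091,25.76
8,2018,0.103,17.07
8,2019,0.055,16.19
8,others,0.094,22.49
9,2018,0.054,15.17
9,2019,0.044,15.08
9,others,0.094,18.80
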