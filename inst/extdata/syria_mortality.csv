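sex,age_lower,age_upper,rate
M,25,35,0.0015
M,35,45,0.0025
M,45,55,0.006
M,55,65,0.014
M,65,75,0.035
M,75,,0.10
F,25,35,0.0010
F,35,45,0.0018
F,45,55,0.004
F,55,65,0.010
F,65,75,0.028
F,75,,0.09
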