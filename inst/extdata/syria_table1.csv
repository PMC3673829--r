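sex,band,year,count,prevalence_pct
M,25-34,2003,16995,1.2
M,25-34,2006,37073,2.2
M,25-34,2011,87962,4
M,25-34,2022,249919,11.3
M,35-44,2003,28483,3.2
M,35-44,2006,57424,5.4
M,35-44,2011,119992,8.6
M,35-44,2022,325066,15.7
M,45-54,2003,66424,12.2
M,45-54,2006,91985,14.3
M,45-54,2011,146472,17.4
M,45-54,2022,329564,23.9
M,55-64,2003,82300,27
M,55-64,2006,95620,27.2
M,55-64,2011,126473,26.7
M,55-64,2022,245785,30.5
M,65-74,2003,47502,27
M,65-74,2006,56226,28.8
M,65-74,2011,73564,31.5
M,65-74,2022,129752,33.3
M,75+,2003,20797,27
M,75+,2006,24638,28
M,75+,2011,32497,30.9
M,75+,2022,52998,37
F,25-34,2003,6682,0.5
F,25-34,2006,26976,1.6
F,25-34,2011,77663,3.7
F,25-34,2022,231184,10.9
F,35-44,2003,29348,3.3
F,35-44,2006,63648,6.1
F,35-44,2011,139289,10.2
F,35-44,2022,388171,19.8
F,45-54,2003,125064,22.4
F,45-54,2006,151993,23.1
F,45-54,2011,212463,25.3
F,45-54,2022,419033,32.1
F,55-64,2003,134372,42.3
F,55-64,2006,148746,40.7
F,55-64,2011,185811,37.7
F,55-64,2022,322827,40.7
F,65-74,2003,87573,42.3
F,65-74,2006,97922,43.1
F,65-74,2011,117106,44.6
F,65-74,2022,167225,38.9
F,75+,2003,40655,42.3
F,75+,2006,43758,38.9
F,75+,2011,54410,37.9
F,75+,2022,83289,41
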