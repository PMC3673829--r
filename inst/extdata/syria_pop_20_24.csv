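year,sex,count
2003,M,695583
2006,M,887532
2011,M,1075658
2022,M,1137136
2003,F,756729
2006,F,809564
2011,F,1063248
2022,F,1074674
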