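date,time,cows,TP,TN,FP,FN,reported_pct
3 September 2022,AM,56,1217,0,0,0,100
3 September 2022,PM,56,1273,0,4,0,99.69
4 September 2022,AM,56,1240,0,0,0,100
4 September 2022,PM,64,1836,1,4,0,99.95
5 September 2022,AM,64,1736,0,0,0,100
5 September 2022,PM,64,1477,0,0,0,100
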