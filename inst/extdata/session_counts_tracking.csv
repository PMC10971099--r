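date,time,cows,GT,FP,FN,IDS,reported_pct
3 September 2022,AM,56,1247,0,0,0,100
3 September 2022,PM,56,1297,0,2,3,99.61
4 September 2022,AM,56,1257,0,0,0,100
4 September 2022,PM,64,1843,1,0,1,99.89
5 September 2022,AM,64,1778,0,0,0,100
5 September 2022,PM,64,1498,0,0,0,100
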