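ID,TIME,EVID,AMT,DUR,DV,BLQ,EGFR_CKDEPI,ABX
1,0,1,2000,0.5,,0,95,1
1,1,0,,,52,0,95,1
1,8,0,,,18,0,95,1
2,0,1,1000,0.5,,0,40,0
2,2,0,,,30,0,40,0
2,6,0,,,12,0,40,0
2,12,1,1000,0.5,,0,40,0
3,0,1,1000,0.5,,0,20,0
3,3,0,,,25,0,20,0
3,20,0,,,,1,20,0
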