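lct_ms,inversion1_ms,inversion2_ms,inversion3_ms
550,288,323,353
660,329,426,476
800,380,557,632
960,439,706,808
1150,508,833,1016
1390,596,1107,1275
1670,699,1368,1574
2000,820,1677,1919
2400,967,2050,2329
2900,1150,2517,2828
3500,1370,3077,3407
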