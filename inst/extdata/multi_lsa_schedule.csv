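# syringe_capacity_uL: 40
time_s,volume_uL,syringe_conc_uM
0,1,1000
60,1,1000
120,1,1000
180,1,1000
240,1,1000
300,1,1000
360,1,1000
420,1,1000
480,1,1000
540,1,1000
600,1,1000
660,1,1000
720,1,1000
780,1,1000
840,1,1000
900,1,1000
960,1,1000
1020,1,1000
1080,1,1000
1140,1,1000
1200,1,1000
1260,1,1000
1320,1,1000
1380,1,1000
1440,1,1000
1500,1,1000
1560,1,1000
1620,1,1000
1680,1,1000
1740,1,1000
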