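energy_kev,photoelectric_cm2_g,incoherent_cm2_g
10,4.840,0.110
15,1.320,0.130
20,0.5230,0.1450
30,0.1460,0.1600
40,0.0577,0.1650
50,0.0288,0.1660
60,0.0160,0.1640
80,0.00635,0.1590
100,0.00306,0.1520
150,0.000840,0.1370
200,0.000338,0.1250
300,0.0000970,0.1070
400,0.0000410,0.0953
500,0.0000215,0.0867
600,0.0000130,0.0800
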