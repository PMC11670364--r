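# Soft tissue (ICRU-44-like composition), basis density 1.06 g/cm3.
# Approximate compilation; log-log interpolation between rows.
# density_g_cm3: 1.060
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g
10      5.367     4.870
15      1.693     1.354
20      0.8205    0.5420
30      0.3783    0.1538
40      0.2685    0.0689
50      0.2262    0.04190
60      0.2048    0.03170
80      0.1823    0.02580
100     0.1693    0.02530
150     0.1492    0.02750
200     0.1358    0.02940
300     0.1175    0.03170
400     0.1051    0.03250
500     0.09593   0.03270
600     0.08873   0.03260
800     0.07792   0.03180
1000    0.07006   0.03080
1250    0.06262   0.02940
1500    0.05699   0.02810
2000    0.04893   0.02580
3000    0.03929   0.02260
4000    0.03367   0.02040
5000    0.02998   0.01890
6000    0.02739   0.01780
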