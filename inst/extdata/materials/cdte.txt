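# Cadmium telluride, density 5.85 g/cm3.
# Approximate compilation (K edges near 26.7 and 31.8 keV coarsely
# represented by close energy pairs); log-log interpolation between rows.
# Intended for megavoltage slab-attenuation estimates; the diagnostic-energy
# region is approximate.
# density_g_cm3: 5.850
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g
10      118.0     95.00
15      40.50     33.00
20      18.60     15.00
26.70   8.530     6.800
26.72   19.50     12.00
31.80   12.60     8.500
31.82   19.90     12.50
40      11.10     7.500
50      6.320     4.400
60      3.980     2.900
80      1.862     1.350
100     1.033     0.7200
150     0.4100    0.2420
200     0.2100    0.1250
300     0.1160    0.05700
400     0.09300   0.03900
500     0.08200   0.03150
600     0.07400   0.02770
800     0.06400   0.02390
1000    0.05700   0.02190
1250    0.05200   0.02040
1500    0.04800   0.01960
2000    0.04300   0.01910
3000    0.03730   0.01870
4000    0.03530   0.01860
5000    0.03430   0.01860
6000    0.03400   0.01870
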