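# Cortical bone (ICRU-44-like composition), basis density 1.85 g/cm3.
# Approximate compilation; log-log interpolation between rows.
# density_g_cm3: 1.850
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g
10      28.51     26.80
15      9.032     8.388
20      4.001     3.601
30      1.331     1.070
40      0.6655    0.4507
50      0.4242    0.2336
60      0.3148    0.1400
80      0.2229    0.06896
100     0.1855    0.04585
150     0.1480    0.03183
200     0.1309    0.03003
300     0.1113    0.03032
400     0.09908   0.03004
500     0.09022   0.02950
600     0.08332   0.02892
800     0.07308   0.02780
1000    0.06566   0.02680
1250    0.05871   0.02565
1500    0.05346   0.02451
2000    0.04607   0.02255
3000    0.03745   0.01997
4000    0.03310   0.01845
5000    0.03062   0.01747
6000    0.02899   0.01678
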