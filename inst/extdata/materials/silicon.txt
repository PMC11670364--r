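# Silicon, density 2.33 g/cm3.
# Approximate compilation; log-log interpolation between rows.
# density_g_cm3: 2.330
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g
10      33.89     32.60
15      10.34     9.790
20      4.464     4.080
30      1.436     1.164
40      0.7012    0.4890
50      0.4385    0.2576
60      0.3207    0.1576
80      0.2228    0.07870
100     0.1835    0.05270
150     0.1448    0.03620
200     0.1275    0.03340
300     0.1082    0.03270
400     0.09614   0.03180
500     0.08748   0.03080
600     0.08077   0.02970
800     0.07082   0.02790
1000    0.06361   0.02640
1250    0.05688   0.02480
1500    0.05183   0.02350
2000    0.04480   0.02150
3000    0.03607   0.01900
4000    0.03240   0.01770
5000    0.02967   0.01690
6000    0.02788   0.01650
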