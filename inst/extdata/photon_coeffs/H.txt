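# element: H
# Z: 1
# atomic_mass: 1.008
# density: 8.375e-05
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 7.217 6.82
1.5 2.148 1.752
2 1.059 0.6643
3 0.5612 0.2206
4 0.4546 0.0995
5 0.4193 0.0486
6 0.4042 0.0283
8 0.3914 0.0135
10 0.3854 0.00986
15 0.3764 0.01102
20 0.3695 0.01331
30 0.357 0.01868
40 0.3458 0.02315
50 0.3355 0.02709
60 0.326 0.03053
80 0.3091 0.0362
100 0.2944 0.04063
150 0.2651 0.04813
200 0.2429 0.05254
300 0.2112 0.05695
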