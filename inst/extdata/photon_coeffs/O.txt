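# element: O
# Z: 8
# atomic_mass: 15.999
# density: 0.001332
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 4590.9 4576.3
1.5 1549.1 1544.7
2 694.95 692.63
3 217.13 215.49
4 93.153 92.218
5 47.892 47.151
6 27.694 27.077
8 11.627 11.163
10 5.9519 5.5657
15 1.8364 1.5457
20 0.86505 0.61796
30 0.37794 0.17296
40 0.25854 0.075306
50 0.21322 0.044138
60 0.19077 0.032073
80 0.1679 0.024681
100 0.15511 0.023549
150 0.13606 0.025058
200 0.12366 0.026788
300 0.10693 0.028766
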