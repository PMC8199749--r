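# element: Ce
# Z: 58
# atomic_mass: 140.116
# density: 6.77
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 9800.7 9791.7
1.14926 7078.2 7069.3
1.32079 6294.1 6285.4
1.51793 4819 4810.5
1.7445 3512.2 3504
2.00488 2542 2534.1
2.30412 1828.3 1820.7
2.64803 1307 1299.8
3.04327 929.52 922.64
3.4975 657.49 651.02
4.01954 463.59 457.55
4.61948 326.2 320.62
5.30898 229.11 223.99
5.723 190.6 185.72
5.723 500.74 471.21
6.10139 469.03 442.63
6.164 460.12 434.32
6.164 622.34 589.19
6.549 537.66 509.91
6.549 587.1 540.46
7.01207 517.95 478.87
8.05868 362.73 337.78
9.2615 252.87 236.72
10.6439 175.57 164.94
12.2325 121.59 114.43
14.0583 83.932 78.973
16.1567 57.873 54.332
18.5682 39.885 37.279
21.3396 27.48 25.512
24.5248 18.93 17.414
28.1853 13.03 11.845
32.3922 8.9559 8.0213
37.2269 6.1716 5.4274
40.443 4.9918 4.3359
40.443 23.782 7.6983
42.7834 20.71 7.3912
49.1691 15.817 6.8955
56.508 10.979 5.5165
64.9423 7.6023 4.2443
74.6355 5.2556 3.1756
85.7754 3.6198 2.319
98.5781 2.492 1.6639
113.292 1.7268 1.1839
130.201 1.2068 0.83784
149.635 0.85274 0.59142
171.969 0.61103 0.41763
197.637 0.44545 0.29601
227.136 0.33148 0.21144
261.038 0.25253 0.15292
300 0.19737 0.1126
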