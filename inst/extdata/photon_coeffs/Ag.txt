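# element: Ag
# Z: 47
# atomic_mass: 107.868
# density: 10.49
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 6792.1 6784.3
1.14926 4973.6 4965.9
1.32079 3618.5 3610.9
1.51793 2615.9 2608.4
1.7445 1878.6 1871.3
2.00488 1343.6 1336.6
2.30412 957.04 950.3
2.64803 678.55 672.12
3.04327 479.43 473.35
3.351 378.42 372.59
3.351 1224 1191.1
3.524 1133.2 1103.5
3.524 1402.9 1367.7
3.806 1280.4 1249.8
3.806 1381.2 1330.8
4.01954 1217.3 1174.4
4.61948 897.49 868.55
5.30898 628.05 609
6.10139 437.53 424.71
7.01207 303.6 294.73
8.05868 209.89 203.55
9.2615 144.68 140
10.6439 99.476 95.902
12.2325 68.325 65.523
14.0583 46.904 44.665
16.1567 32.172 30.363
18.5682 22.056 20.586
21.3396 15.137 13.938
24.5248 10.406 9.4243
25.514 9.4348 8.5018
25.514 50.53 18.868
28.1853 43.14 18.516
32.3922 29.973 14.959
37.2269 20.726 11.576
42.7834 14.292 8.696
49.1691 9.8348 6.3878
56.508 6.7502 4.6045
64.9423 4.6337 3.2736
74.6355 3.1867 2.3028
85.7754 2.1967 1.6042
98.5781 1.5236 1.111
113.292 1.0678 0.7679
130.201 0.7585 0.53096
149.635 0.54814 0.36831
171.969 0.40449 0.25727
197.637 0.3058 0.18182
227.136 0.23745 0.13077
261.038 0.18958 0.096351
300 0.15559 0.073215
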