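# element: Ta
# Z: 73
# atomic_mass: 180.948
# density: 16.65
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 3357.3 3346
1.14926 2545.9 2534.7
1.32079 1925.4 1914.4
1.51793 1450.9 1440.1
1.7445 6320 6309.5
2.00488 3694.2 3683.9
2.30412 2868.9 2859
2.64803 2325.6 2316
3.04327 1752.1 1742.9
3.4975 1255.8 1247.1
4.01954 894.74 886.48
4.61948 635.19 627.47
5.30898 449.29 442.15
6.10139 316.98 310.44
7.01207 223.26 217.34
8.05868 157.04 151.73
9.2615 110.29 105.58
9.881 94.192 89.742
9.881 221.13 192.57
10.6439 201.43 176.85
11.136 179.87 158.42
11.136 244.44 216.74
11.682 218.59 194.46
11.682 227.37 188.52
12.2325 212.62 177.61
14.0583 156.31 133.19
16.1567 109.22 94.465
18.5682 76.119 66.58
21.3396 52.932 46.656
24.5248 36.74 32.521
28.1853 25.462 22.556
32.3922 17.633 15.576
37.2269 12.224 10.725
42.7834 8.4918 7.3654
49.1691 5.9143 5.0422
56.508 4.1354 3.4408
64.9423 2.9132 2.3458
67.416 2.6753 2.1338
67.416 10.686 3.0742
74.6355 9.0966 3.1803
85.7754 6.3896 2.7046
98.5781 4.481 2.1681
113.292 3.1482 1.6759
130.201 2.2186 1.2638
149.635 1.5614 0.93065
171.969 1.1065 0.67765
197.637 0.79294 0.49122
227.136 0.57598 0.35587
261.038 0.42514 0.25865
300 0.3196 0.18937
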