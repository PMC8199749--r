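# element: W
# Z: 74
# atomic_mass: 183.84
# density: 19.3
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 3526 3514.5
1.14926 2673.5 2662.2
1.32079 2020.2 2009
1.51793 1521.3 1510.4
1.7445 1140.7 1130
2.00488 3837.1 3826.7
2.30412 2988.8 2978.7
2.64803 2417 2407.3
3.04327 1814.4 1805.1
3.4975 1301.9 1293.1
4.01954 928.63 920.27
4.61948 659.74 651.92
5.30898 466.94 459.71
6.10139 329.56 322.94
7.01207 232.21 226.2
8.05868 163.39 158
9.2615 114.79 110
10.207 90.274 85.887
10.207 210.64 181.35
10.6439 189.77 164
11.544 169.69 147.99
11.544 230.84 202.73
12.1 206.73 182.21
12.1 214.99 175.42
12.2325 210.72 172.18
14.0583 161.76 135.37
16.1567 113.15 96.389
18.5682 78.927 68.156
21.3396 54.931 47.9
24.5248 38.157 33.476
28.1853 26.458 23.267
32.3922 18.33 16.097
37.2269 12.714 11.103
42.7834 8.8365 7.6367
49.1691 6.1592 5.2364
56.508 4.3107 3.579
64.9423 3.0386 2.4425
69.525 2.5875 2.0418
69.525 10.18 2.8922
74.6355 9.3723 3.0729
85.7754 6.5914 2.6659
98.5781 4.6314 2.1653
113.292 3.2573 1.6877
130.201 2.298 1.2806
149.635 1.6214 0.94921
171.969 1.1492 0.69336
197.637 0.82341 0.50384
227.136 0.5978 0.36567
261.038 0.44084 0.2661
300 0.33093 0.19495
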