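# element: Tm
# Z: 69
# atomic_mass: 168.934
# density: 9.32
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 2782.1 2771.3
1.14926 2124.5 2113.8
1.32079 1614.6 1604.1
1.51793 5791 5780.7
1.7445 4450.4 4440.3
2.00488 3648.2 3638.3
2.30412 2798.5 2789
2.64803 2116.6 2107.5
3.04327 1521.1 1512.3
3.4975 1084.7 1076.3
4.01954 770.55 762.7
4.61948 545.36 538.05
5.30898 384.9 378.16
6.10139 271.13 264.98
7.01207 190.65 185.1
8.05868 133.9 128.94
8.648 112.74 108.06
8.648 271.52 242.72
9.2615 251.24 225.94
9.617 228.96 206.32
9.617 313.22 283.85
10.116 275.51 250.34
10.116 286.56 246.11
10.6439 264.96 229.03
12.2325 194.52 170.76
14.0583 135.77 120.56
16.1567 94.514 84.632
18.5682 65.64 59.099
21.3396 45.49 41.059
24.5248 31.491 28.412
28.1853 21.779 19.582
32.3922 15.056 13.447
37.2269 10.421 9.213
42.7834 7.2214 6.2931
49.1691 5.0136 4.2836
56.508 3.4996 2.9127
59.39 3.1062 2.5584
59.39 13.087 3.8855
64.9423 11.484 4.0388
74.6355 8.0345 3.434
85.7754 5.6126 2.7532
98.5781 3.9186 2.1239
113.292 2.7415 1.5973
130.201 1.9142 1.1727
149.635 1.3433 0.84958
171.969 0.9522 0.61208
197.637 0.68347 0.4401
227.136 0.49808 0.31696
261.038 0.36951 0.22953
300 0.27974 0.16785
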