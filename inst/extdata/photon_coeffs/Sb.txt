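# element: Sb
# Z: 51
# atomic_mass: 121.76
# density: 6.691
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 8316.4 8308.3
1.14926 6143.8 6135.8
1.32079 4505.1 4497.2
1.51793 3273.8 3266.2
1.7445 2363.4 2356
2.00488 1696.5 1689.3
2.30412 1210.9 1204
2.64803 860.43 853.85
3.04327 608.95 602.72
3.4975 428.41 422.55
4.01954 300.83 295.38
4.132 282.57 277.19
4.132 921.99 888.39
4.38 781.93 754.02
4.38 963.96 930.91
4.61948 928.88 898.32
4.698 895.71 866.44
4.698 983.01 933.87
5.30898 752.83 718.25
6.10139 527.53 505.12
7.01207 367.79 353.02
8.05868 255.45 245.49
9.2615 176.72 169.82
10.6439 121.81 116.87
12.2325 83.861 80.214
14.0583 57.69 54.913
16.1567 39.656 37.492
18.5682 27.246 25.531
21.3396 18.71 17.338
24.5248 12.858 11.752
28.1853 8.8343 7.9379
30.491 7.2025 6.3999
30.491 37 12.984
32.3922 31.865 12.282
37.2269 24.329 11.227
42.7834 16.861 8.8612
49.1691 11.65 6.7506
56.508 8.0328 5.012
64.9423 5.5287 3.6461
74.6355 3.8053 2.6117
85.7754 2.6196 1.8454
98.5781 1.8104 1.2922
113.292 1.262 0.90121
130.201 0.88964 0.62752
149.635 0.63632 0.43741
171.969 0.46341 0.30619
197.637 0.34483 0.21613
227.136 0.26298 0.1546
261.038 0.20596 0.11274
300 0.16578 0.084339
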