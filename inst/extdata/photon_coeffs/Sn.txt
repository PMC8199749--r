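# element: Sn
# Z: 50
# atomic_mass: 118.71
# density: 7.31
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 7915.1 7907.1
1.14926 5834.8 5826.9
1.32079 4266.3 4258.5
1.51793 3094.9 3087.4
1.7445 2231.3 2224
2.00488 1599.7 1592.6
2.30412 1140.5 1133.7
2.64803 810.04 803.52
3.04327 572.9 566.73
3.4975 402.8 397
3.929 302 296.52
3.929 996.51 962.87
4.01954 934.61 903.32
4.156 851.79 823.59
4.156 1051.2 1017.8
4.465 972.67 943.23
4.465 1065.7 1016.4
4.61948 976.66 932.41
5.30898 718.51 688.86
6.10139 502.57 483.22
7.01207 349.98 337.1
8.05868 242.79 233.99
9.2615 167.77 161.58
10.6439 115.55 111.06
12.2325 79.512 76.138
14.0583 54.669 52.064
16.1567 37.561 35.509
18.5682 25.792 24.154
21.3396 17.705 16.387
24.5248 12.167 11.1
28.1853 8.359 7.4899
29.2 7.6576 6.8281
29.2 39.741 14.144
32.3922 33.562 13.943
37.2269 23.323 11.35
42.7834 16.139 8.83
49.1691 11.14 6.6587
56.508 7.6744 4.9057
64.9423 5.2771 3.5459
74.6355 3.6315 2.528
85.7754 2.5009 1.7798
98.5781 1.7299 1.2428
113.292 1.2075 0.86488
130.201 0.85286 0.60123
149.635 0.61153 0.41861
171.969 0.44676 0.2929
197.637 0.3337 0.20681
227.136 0.25558 0.14811
261.038 0.20109 0.10826
300 0.16261 0.081268
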