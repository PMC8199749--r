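# element: Bi
# Z: 83
# atomic_mass: 208.98
# density: 9.78
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 5235.8 5223.1
1.14926 4010.2 3997.6
1.32079 3052.9 3040.5
1.51793 2310 2297.9
1.7445 1736.6 1724.8
2.00488 1293.1 1281.6
2.30412 957.43 946.21
2.64803 2651.7 2640.9
3.04327 1957.3 1946.9
3.4975 1605.2 1595.4
4.01954 1265 1255.7
4.61948 905.6 896.92
5.30898 645.2 637.15
6.10139 457.7 450.31
7.01207 323.84 317.11
8.05868 228.64 222.57
9.2615 161.11 155.69
10.6439 113.35 108.55
12.2325 79.763 75.563
13.419 63.623 59.79
13.419 140.15 112.7
14.0583 124.73 100.99
15.711 102.91 84.828
15.711 140.92 117.32
16.1567 131.92 110.19
16.388 128.06 107.13
16.388 133.14 99.295
18.5682 106.86 82.382
21.3396 74.958 59.474
24.5248 52.463 42.57
28.1853 36.623 30.217
32.3922 25.52 21.291
37.2269 17.772 14.907
42.7834 12.401 10.394
49.1691 8.681 7.2219
56.508 6.1047 5.0014
64.9423 4.319 3.4529
74.6355 3.0809 2.3784
85.7754 2.2211 1.6367
90.526 1.9765 1.4276
90.526 6.7805 1.7923
98.5781 6.0392 1.9082
113.292 4.3004 1.6705
130.201 3.0635 1.3684
149.635 2.1839 1.0742
171.969 1.5647 0.82241
197.637 1.1277 0.6192
227.136 0.81913 0.46125
261.038 0.60096 0.3416
300 0.44636 0.25264
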