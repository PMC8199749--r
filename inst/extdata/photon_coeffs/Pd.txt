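# element: Pd
# Z: 46
# atomic_mass: 106.42
# density: 12.02
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 6306.6 6299
1.14926 4610.9 4603.4
1.32079 3350.1 3342.6
1.51793 2416 2408.8
1.7445 1734.5 1727.4
2.00488 1240.1 1233.3
2.30412 882.49 875.91
2.64803 625.47 619.21
3.04327 441.84 435.94
3.173 400.51 394.71
3.173 1281.4 1249.6
3.33 1221.5 1192.1
3.33 1518.2 1483.2
3.4975 1478.7 1445.8
3.604 1378.1 1347.9
3.604 1479.5 1430
4.01954 1196.3 1159.2
4.61948 840.54 816.31
5.30898 587.26 571.15
6.10139 408.61 397.62
7.01207 283.13 275.4
8.05868 195.55 189.93
9.2615 134.69 130.47
10.6439 92.548 89.272
12.2325 63.533 60.931
14.0583 43.592 41.494
16.1567 29.876 28.169
18.5682 20.478 19.085
21.3396 14.054 12.914
24.35 9.9308 8.9801
24.35 53.849 20.487
28.1853 40.721 18.737
32.3922 28.225 14.839
37.2269 19.49 11.331
42.7834 13.425 8.4291
49.1691 9.2273 6.1437
56.508 6.3258 4.3996
64.9423 4.3405 3.1125
74.6355 2.9845 2.1803
85.7754 2.058 1.5138
98.5781 1.4289 1.0456
113.292 1.0029 0.72116
130.201 0.71401 0.49781
149.635 0.51754 0.34496
171.969 0.38336 0.24089
197.637 0.29113 0.17037
227.136 0.22719 0.12278
261.038 0.18235 0.090771
300 0.15043 0.06931
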