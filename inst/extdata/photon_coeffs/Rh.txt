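# element: Rh
# Z: 45
# atomic_mass: 102.906
# density: 12.41
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 5938.8 5931.4
1.14926 4337.4 4330
1.32079 3144.5 3137.2
1.51793 2266.3 2259.2
1.7445 1626.7 1619.8
2.00488 1162.7 1156
2.30412 826.82 820.43
2.64803 586.04 579.96
3.004 431.1 425.32
3.004 1479.3 1445.6
3.04327 1446 1413.2
3.146 1347.8 1317.7
3.146 1673 1637.2
3.412 1510.3 1479.6
3.412 1638.4 1587.6
3.4975 1551.5 1504
4.01954 1142.1 1110.2
4.61948 800.73 779.77
5.30898 558.72 544.63
6.10139 388.27 378.53
7.01207 268.68 261.73
8.05868 185.4 180.27
9.2615 127.61 123.69
10.6439 87.618 84.532
12.2325 60.121 57.644
14.0583 41.22 39.207
16.1567 28.234 26.588
18.5682 19.352 18.004
21.3396 13.283 12.176
23.22 10.667 9.6784
23.22 58.473 22.74
24.5248 51.158 21.404
28.1853 39.069 19.177
32.3922 27.049 14.937
37.2269 18.656 11.269
42.7834 12.836 8.3066
49.1691 8.808 6.0062
56.508 6.035 4.2767
64.9423 4.1393 3.0111
74.6355 2.8458 2.1007
85.7754 1.9633 1.4537
98.5781 1.3645 1.0015
113.292 0.95935 0.68929
130.201 0.68463 0.47505
149.635 0.49783 0.32886
171.969 0.37024 0.22962
197.637 0.28251 0.16255
227.136 0.22162 0.1174
261.038 0.17884 0.087128
300 0.14833 0.066879
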