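# element: Au
# Z: 79
# atomic_mass: 196.967
# density: 19.32
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 4456.7 4444.4
1.14926 3413.4 3401.3
1.32079 2597.9 2585.9
1.51793 1955.4 1943.6
1.7445 1460.2 1448.6
2.00488 1085.6 1074.3
2.30412 3075 3064.1
2.64803 2377.5 2366.9
3.04327 1963.1 1953.1
3.4975 1553.9 1544.3
4.01954 1114.2 1105.2
4.61948 794.86 786.47
5.30898 564.32 556.56
6.10139 399.46 392.35
7.01207 282.01 275.55
8.05868 198.76 192.94
9.2615 139.88 134.7
10.6439 98.283 93.709
11.919 74.337 70.229
11.919 167.89 139.51
12.2325 157.88 131.58
13.734 128.66 108.92
13.734 175.74 150.06
14.0583 166.43 142.43
14.353 158.71 136.09
14.353 165.02 128.49
16.1567 134.62 107.6
18.5682 94.339 77.237
21.3396 65.94 55.006
24.5248 45.99 38.901
28.1853 32.002 27.323
32.3922 22.227 19.067
37.2269 15.453 13.254
42.7834 10.764 9.1819
49.1691 7.5226 6.3405
56.508 5.2803 4.3644
64.9423 3.729 2.9955
74.6355 2.6565 2.0526
80.725 2.2204 1.6721
80.725 8.1025 2.2141
85.7754 7.0287 2.1721
98.5781 5.4285 2.1011
113.292 3.8453 1.7275
130.201 2.722 1.3565
149.635 1.9348 1.0366
171.969 1.3824 0.77759
197.637 0.99439 0.57615
227.136 0.72158 0.42369
261.038 0.52957 0.31055
300 0.39407 0.22785
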