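# element: Pb
# Z: 82
# atomic_mass: 207.2
# density: 11.35
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 5018.6 5006.1
1.14926 3841.4 3829
1.32079 2923.5 2911.3
1.51793 2211.1 2199.1
1.7445 1659.5 1647.8
2.00488 1234.2 1222.8
2.30412 913.67 902.59
2.64803 3739.1 3728.4
3.04327 1872.6 1862.4
3.4975 1542.2 1532.5
4.01954 1220.5 1211.3
4.61948 872.89 864.32
5.30898 621.23 613.29
6.10139 440.46 433.17
7.01207 311.45 304.83
8.05868 219.77 213.8
9.2615 154.8 149.47
10.6439 108.88 104.17
12.2325 76.59 72.465
13.035 65.728 61.85
13.035 145.72 118
14.0583 132.29 108.58
15.2 108.13 89.634
15.2 147.99 123.85
15.861 134.25 112.89
15.861 139.57 105.02
16.1567 134.2 101.39
18.5682 103.08 80.653
21.3396 72.243 58.03
24.5248 50.516 41.411
28.1853 35.234 29.315
32.3922 24.527 20.602
37.2269 17.072 14.396
42.7834 11.908 10.021
49.1691 8.3344 6.9517
56.508 5.8608 4.8075
64.9423 4.1469 3.3146
74.6355 2.9591 2.2803
85.7754 2.1347 1.5678
88.005 2.0265 1.475
88.005 7.0503 1.8762
98.5781 5.8595 1.9558
113.292 4.1664 1.681
130.201 2.9639 1.3608
149.635 2.1121 1.0605
171.969 1.5127 0.80757
197.637 1.09 0.60548
227.136 0.79173 0.44952
261.038 0.58101 0.33202
300 0.43179 0.24504
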