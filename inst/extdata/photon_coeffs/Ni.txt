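# element: Ni
# Z: 28
# atomic_mass: 58.693
# density: 8.902
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 9611.7 9587.1
1.14926 7851.5 7823.4
1.32079 5622.3 5603
1.51793 3990.1 3976.5
1.7445 2813 2803
2.00488 1973.5 1965.7
2.30412 1377.3 1371.1
2.64803 957.22 951.95
3.04327 662.52 657.97
3.4975 456.55 452.54
4.01954 313.57 310.02
4.61948 214.99 211.83
5.30898 147.17 144.37
6.10139 100.65 98.2
7.01207 68.801 66.663
8.05868 47.011 45.163
8.333 43.248 41.46
8.333 302.07 203.41
9.2615 254.27 179.12
10.6439 176.86 131.04
12.2325 122.24 94.391
14.0583 84.108 67.17
16.1567 57.624 47.293
18.5682 39.275 32.942
21.3396 26.683 22.758
24.5248 18.082 15.609
28.1853 12.224 10.632
32.3922 8.2526 7.1976
37.2269 5.571 4.846
42.7834 3.7618 3.2422
49.1691 2.5543 2.1641
56.508 1.7487 1.4421
64.9423 1.2113 0.96039
74.6355 0.85243 0.64026
85.7754 0.61245 0.42832
98.5781 0.45147 0.28857
113.292 0.34294 0.19682
130.201 0.26919 0.13687
149.635 0.21848 0.097904
171.969 0.18305 0.072739
197.637 0.15773 0.056597
227.136 0.13912 0.04632
261.038 0.12499 0.039828
300 0.11385 0.035751
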