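# element: Mo
# Z: 42
# atomic_mass: 95.95
# density: 10.22
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 4748.5 4741.5
1.14926 3447.3 3440.5
1.32079 2492.4 2485.7
1.51793 1794.5 1788
1.7445 1284.9 1278.6
2.00488 916.11 910
2.30412 650.94 645.1
2.52 525.45 519.78
2.52 1959.3 1924.1
2.625 1773.7 1742.3
2.625 2206 2168.4
2.64803 2173.6 2136.7
2.866 1958.6 1927
2.866 2129 2076.4
3.04327 1835.8 1792.1
3.4975 1353.6 1324.1
4.01954 949.13 929.57
4.61948 662.43 649.15
5.30898 460.3 450.99
6.10139 318.42 311.67
7.01207 219.67 214.59
8.05868 151.21 147.26
9.2615 103.86 100.7
10.6439 71.202 68.631
12.2325 48.755 46.639
14.0583 33.355 31.607
16.1567 22.837 21.392
18.5682 15.656 14.461
20 12.911 11.826
20 73.443 30.573
21.3396 68.635 30.921
24.5248 47.78 24.776
28.1853 33.071 19.072
32.3922 22.782 14.262
37.2269 15.652 10.443
42.7834 10.719 7.5109
49.1691 7.3269 5.3253
56.508 5.0091 3.7347
64.9423 3.4293 2.5955
74.6355 2.3548 1.7901
85.7754 1.6252 1.2272
98.5781 1.1326 0.83929
113.292 0.80014 0.57425
130.201 0.57528 0.39414
149.635 0.42266 0.27234
171.969 0.31849 0.19036
197.637 0.24683 0.1354
227.136 0.19698 0.098715
261.038 0.16182 0.074308
300 0.13656 0.058116
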