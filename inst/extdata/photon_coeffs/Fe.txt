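# element: Fe
# Z: 26
# atomic_mass: 55.845
# density: 7.874
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 8836.5 8812.2
1.14926 6342.3 6325.5
1.32079 4508.3 4496.3
1.51793 3181.6 3172.6
1.7445 2233 2226.1
2.00488 1560.2 1554.5
2.30412 1085.3 1080.5
2.64803 751.93 747.74
3.04327 518.84 515.12
3.4975 356.33 353
4.01954 244.2 241.22
4.61948 167.17 164.5
5.30898 114.33 111.96
6.10139 78.129 76.047
7.01207 53.363 51.548
7.112 51.757 49.962
7.112 373.89 270.71
8.05868 299.9 226.37
9.2615 208.52 163.69
10.6439 144.03 116.77
12.2325 99.053 82.465
14.0583 67.828 57.699
16.1567 46.178 39.959
18.5682 31.34 27.475
21.3396 21.214 18.77
24.5248 14.329 12.747
28.1853 9.6579 8.6034
32.3922 6.4981 5.7695
37.2269 4.3739 3.8487
42.7834 2.9579 2.5615
49.1691 2.0148 1.7018
56.508 1.3867 1.1296
64.9423 0.96819 0.75014
74.6355 0.68904 0.49931
85.7754 0.50238 0.33413
98.5781 0.37706 0.2258
113.292 0.29235 0.15506
130.201 0.23452 0.1091
149.635 0.19447 0.07943
171.969 0.16615 0.060405
197.637 0.14561 0.048307
227.136 0.13023 0.040685
261.038 0.11828 0.035928
300 0.10863 0.032982
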