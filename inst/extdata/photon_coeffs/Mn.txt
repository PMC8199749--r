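# element: Mn
# Z: 25
# atomic_mass: 54.938
# density: 7.3
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 7842.1 7825.9
1.14926 5597.2 5585.7
1.32079 3961.8 3953.2
1.51793 2788 2781.3
1.7445 1952.8 1947.3
2.00488 1361.8 1357.1
2.30412 945.66 941.56
2.64803 654.04 650.39
3.04327 450.66 447.36
3.4975 309.02 306.03
4.01954 211.61 208.92
4.61948 144.76 142.34
5.30898 98.942 96.793
6.10139 67.58 65.687
6.539 56.348 54.572
6.539 414.84 310.66
7.01207 382.9 292.83
8.05868 267.46 212.35
9.2615 185.28 151.73
10.6439 127.65 107.24
12.2325 87.563 75.116
14.0583 59.741 52.116
16.1567 40.58 35.865
18.5682 27.488 24.526
21.3396 18.573 16.673
24.5248 12.524 11.272
28.1853 8.4314 7.5776
32.3922 5.6573 5.0526
37.2269 3.8086 3.3605
42.7834 2.5783 2.2307
49.1691 1.7599 1.4788
56.508 1.2154 0.97998
64.9423 0.85299 0.65007
74.6355 0.61131 0.43262
85.7754 0.44969 0.28979
98.5781 0.34108 0.19637
113.292 0.26752 0.13552
130.201 0.21714 0.096117
149.635 0.18206 0.070755
171.969 0.15709 0.054555
197.637 0.1388 0.044302
227.136 0.12495 0.037879
261.038 0.11405 0.033898
300 0.10514 0.031453
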