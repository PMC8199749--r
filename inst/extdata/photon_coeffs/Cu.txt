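# element: Cu
# Z: 29
# atomic_mass: 63.546
# density: 8.96
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 9422.8 9392.7
1.097 8217.4 8192.5
1.097 8916.1 8875.3
1.14926 7968 7932.4
1.32079 5918.7 5893.9
1.51793 4205.1 4188
1.7445 2969.3 2957.1
2.00488 2086.3 2077.1
2.30412 1458.7 1451.5
2.64803 1015.1 1009.3
3.04327 703.49 698.54
3.4975 485.28 481
4.01954 333.77 330
4.61948 229.03 225.71
5.30898 156.86 153.94
6.10139 107.32 104.77
7.01207 73.381 71.162
8.05868 50.154 48.242
8.979 37.609 35.908
8.979 257.78 166.89
9.2615 239.93 157.58
10.6439 183.69 128.57
12.2325 127.52 93.936
14.0583 87.941 67.53
16.1567 60.385 47.961
18.5682 41.277 33.685
21.3396 28.093 23.419
24.5248 19.069 16.153
28.1853 12.909 11.057
32.3922 8.7245 7.5175
37.2269 5.8978 5.0849
42.7834 3.9851 3.4158
49.1691 2.7029 2.2855
56.508 1.8468 1.5264
64.9423 1.2753 1.0184
74.6355 0.89361 0.67985
85.7754 0.63824 0.45509
98.5781 0.46695 0.30648
113.292 0.35155 0.20862
130.201 0.27324 0.14449
149.635 0.21955 0.10267
171.969 0.18217 0.075561
197.637 0.15563 0.058093
227.136 0.13627 0.046917
261.038 0.1217 0.039815
300 0.11035 0.035325
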