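# element: V
# Z: 23
# atomic_mass: 50.942
# density: 6.0
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 6255 6243.6
1.14926 4423.9 4415.5
1.32079 3113 3106.5
1.51793 2180.6 2175.4
1.7445 1521 1516.6
2.00488 1056.6 1052.7
2.30412 730.74 727.29
2.64803 503.77 500.65
3.04327 346.29 343.46
3.4975 237.04 234.47
4.01954 162.09 159.76
4.61948 110.73 108.65
5.30898 75.591 73.739
5.465 70.389 68.579
5.465 540.06 428.83
6.10139 449.54 366.1
7.01207 313.41 262.4
8.05868 217 185.92
9.2615 149.39 130.46
10.6439 102.31 90.75
12.2325 69.664 62.563
14.0583 47.262 42.849
16.1567 31.974 29.182
18.5682 21.576 19.768
21.3396 14.528 13.322
24.5248 9.7661 8.9328
28.1853 6.5536 5.9549
32.3922 4.3985 3.9494
37.2269 2.9659 2.6138
42.7834 2.0144 1.7272
49.1691 1.3826 1.1403
56.508 0.96296 0.75305
64.9423 0.68397 0.49836
74.6355 0.49809 0.33144
85.7754 0.37375 0.22247
98.5781 0.29005 0.15166
113.292 0.23314 0.10588
130.201 0.19388 0.076486
149.635 0.16623 0.057759
171.969 0.14623 0.045947
197.637 0.13127 0.038588
227.136 0.11965 0.034069
261.038 0.11025 0.031338
300 0.10236 0.029712
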