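# element: Be
# Z: 4
# atomic_mass: 9.0122
# density: 1.848
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 549.47 548.87
1.14926 364 363.43
1.32079 240.3 239.76
1.51793 158.1 157.59
1.7445 103.67 103.2
2.00488 67.768 67.331
2.30412 44.144 43.742
2.64803 28.697 28.327
3.04327 18.627 18.285
3.4975 12.049 11.73
4.01954 7.8121 7.5126
4.61948 5.0879 4.8034
5.30898 3.3388 3.0668
6.10139 2.2166 1.9553
7.01207 1.4963 1.2451
8.05868 1.0332 0.79208
9.2615 0.73424 0.50322
10.6439 0.54014 0.31932
12.2325 0.41399 0.20316
14.0583 0.3313 0.12995
16.1567 0.27657 0.083961
18.5682 0.2399 0.055219
21.3396 0.21491 0.037407
24.5248 0.19747 0.026524
28.1853 0.18491 0.020026
32.3922 0.17549 0.016333
37.2269 0.16811 0.014446
42.7834 0.16201 0.013709
49.1691 0.15667 0.01371
56.508 0.15179 0.014185
64.9423 0.14715 0.014965
74.6355 0.1426 0.015935
85.7754 0.13805 0.017017
98.5781 0.13346 0.018155
113.292 0.12879 0.019305
130.201 0.12403 0.020433
149.635 0.1192 0.021509
171.969 0.11431 0.022511
197.637 0.10937 0.023421
227.136 0.10443 0.024222
261.038 0.099499 0.024906
300 0.094609 0.025464
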