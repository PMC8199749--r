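# element: Ba
# Z: 56
# atomic_mass: 137.327
# density: 3.5
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 8471 8462.5
1.14926 7588.4 7580
1.32079 5845.7 5837.5
1.51793 4283.1 4275.1
1.7445 3114.5 3106.7
2.00488 2249.7 2242.2
2.30412 1614.9 1607.7
2.64803 1152.5 1145.6
3.04327 818.61 812.08
3.4975 578.21 572.08
4.01954 407.42 401.71
4.61948 286.56 281.27
5.247 208.73 203.83
5.247 559.73 530.4
5.30898 612.68 581.28
5.624 521.02 494.99
5.624 639.53 608.77
5.989 605.64 577.81
5.989 665.89 618.87
6.10139 636.81 592.34
7.01207 464.47 435.11
8.05868 324.49 305.55
9.2615 225.74 213.31
10.6439 156.45 148.13
12.2325 108.1 102.37
14.0583 74.542 70.477
16.1567 51.36 48.384
18.5682 35.367 33.127
21.3396 24.346 22.62
24.5248 16.754 15.404
28.1853 11.517 10.45
32.3922 7.916 7.0656
37.441 5.4191 4.7378
37.441 26.349 8.6932
42.7834 20.6 8.41
49.1691 14.315 6.8616
56.508 9.9158 5.3492
64.9423 6.8539 4.0404
74.6355 4.7307 2.9806
85.7754 3.2545 2.1523
98.5781 2.2421 1.5324
113.292 1.5555 1.0835
130.201 1.089 0.76289
149.635 0.77157 0.53629
171.969 0.55491 0.37753
197.637 0.4065 0.26708
227.136 0.30431 0.19067
261.038 0.23347 0.13807
300 0.18389 0.10199
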