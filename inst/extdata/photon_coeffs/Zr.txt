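# element: Zr
# Z: 40
# atomic_mass: 91.224
# density: 6.506
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 4035.5 4028.9
1.14926 2926.2 2919.8
1.32079 2113.3 2107
1.51793 1516.6 1510.5
1.7445 1084.3 1078.4
2.00488 772.48 766.78
2.223 603.79 598.26
2.223 2366.2 2331.6
2.307 2157.3 2126.2
2.307 2684.4 2647.2
2.532 2352.2 2321.4
2.532 2555.9 2504.6
2.64803 2292.7 2248
3.04327 1692.2 1661.9
3.4975 1188.3 1168.2
4.01954 830.68 816.98
4.61948 578.1 568.45
5.30898 400.27 393.23
6.10139 276.32 270.98
7.01207 190.29 186.11
8.05868 130.79 127.42
9.2615 89.727 86.955
10.6439 61.403 59.101
12.2325 41.976 40.057
14.0583 28.712 27.113
16.1567 19.662 18.331
17.998 14.793 13.634
17.998 86.287 37.957
18.5682 80.233 36.495
21.3396 61.345 32.096
24.5248 42.541 24.73
28.1853 29.339 18.504
32.3922 20.153 13.547
37.2269 13.798 9.7466
42.7834 9.4141 6.906
49.1691 6.4205 4.8415
56.508 4.3816 3.364
64.9423 2.9964 2.3199
74.6355 2.0574 1.59
85.7754 1.4224 1.085
98.5781 0.99462 0.73965
113.292 0.70614 0.50485
130.201 0.5111 0.34605
149.635 0.3787 0.23917
171.969 0.28828 0.16755
197.637 0.22601 0.11977
227.136 0.18261 0.088036
261.038 0.15188 0.06703
300 0.12968 0.053168
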