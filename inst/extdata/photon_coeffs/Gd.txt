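# element: Gd
# Z: 64
# atomic_mass: 157.25
# density: 7.9
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 2181.5 2171.6
1.14926 1680.2 1670.4
1.32079 6809.2 6799.7
1.51793 4825 4815.7
1.7445 4295.7 4286.6
2.00488 3268.4 3259.5
2.30412 2371 2362.5
2.64803 1706.4 1698.2
3.04327 1220.6 1212.8
3.4975 867.3 859.92
4.01954 614.08 607.17
4.61948 433.66 427.25
5.30898 305.56 299.67
6.10139 214.82 209.46
7.01207 150.82 145.99
7.243 139.93 135.21
7.243 349.23 319.22
7.93 307.21 282.39
7.93 415.89 383.92
8.05868 401.44 370.83
8.376 364.85 337.62
8.376 379.67 335.76
9.2615 323.95 289.4
10.6439 226.37 204.4
12.2325 157.68 143.54
14.0583 109.57 100.3
16.1567 75.938 69.74
18.5682 52.513 48.258
21.3396 36.283 33.279
24.5248 25.057 22.876
28.1853 17.292 15.672
32.3922 11.932 10.704
37.2269 8.2335 7.2874
42.7834 5.6865 4.9469
49.1691 3.9423 3.3554
50.239 3.756 3.1862
50.239 16.788 5.1556
56.508 13.686 5.1777
64.9423 9.5384 4.3127
74.6355 6.6344 3.4121
85.7754 4.6049 2.6048
98.5781 3.1968 1.9401
113.292 2.2106 1.4103
130.201 1.5379 1.0142
149.635 1.0799 0.72498
171.969 0.76714 0.5169
197.637 0.55293 0.36878
227.136 0.40557 0.26423
261.038 0.30363 0.19092
300 0.23261 0.13977
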