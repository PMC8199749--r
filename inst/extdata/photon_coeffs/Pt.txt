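# element: Pt
# Z: 78
# atomic_mass: 195.084
# density: 21.45
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 4244.4 4232.4
1.14926 3251 3239
1.32079 2470.8 2459
1.51793 1853.3 1841.7
1.7445 1384.4 1373.1
2.00488 1030.3 1019.3
2.30412 3289 3278.2
2.64803 2489.7 2479.4
3.04327 2005.6 1995.7
3.4975 1495.5 1486.1
4.01954 1071.6 1062.8
4.61948 763.56 755.32
5.30898 541.9 534.27
6.10139 383.37 376.38
7.01207 270.51 264.16
8.05868 190.6 184.89
9.2615 134.1 129.01
10.6439 94.188 89.704
11.564 76.904 72.756
11.564 174.88 146.81
12.2325 151.62 128.07
13.273 135.4 115.61
13.273 184.78 159.06
13.88 166.53 143.93
13.88 173.15 136.69
14.0583 168.9 133.61
16.1567 129.69 105.54
18.5682 90.803 75.47
21.3396 63.414 53.57
24.5248 44.19 37.773
28.1853 30.72 26.456
32.3922 21.324 18.422
37.2269 14.819 12.782
42.7834 10.318 8.8395
49.1691 7.2077 6.0945
56.508 5.057 4.1886
64.9423 3.5694 2.8701
74.6355 2.5423 1.9644
78.395 2.2772 1.7322
78.395 8.4626 2.3351
85.7754 7.4333 2.4583
98.5781 5.2505 2.1221
113.292 3.7069 1.7192
130.201 2.6241 1.3403
149.635 1.8651 1.0188
171.969 1.3263 0.75705
197.637 0.94974 0.55603
227.136 0.68821 0.40685
261.038 0.5058 0.2978
300 0.37781 0.21895
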