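# element: Hf
# Z: 72
# atomic_mass: 178.486
# density: 13.31
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 3190.1 3179
1.14926 2421.5 2410.5
1.32079 1832.7 1821.9
1.51793 1381.7 1371.1
1.7445 4582.3 4571.9
2.00488 3538.4 3528.2
2.30412 2922.7 2912.8
2.64803 2337.4 2327.9
3.04327 1685.8 1676.8
3.4975 1206.7 1198.1
4.01954 859.24 851.1
4.61948 609.53 601.92
5.30898 430.89 423.85
6.10139 303.9 297.46
7.01207 213.99 208.16
8.05868 150.46 145.24
9.2615 105.63 101
9.561 98.114 93.613
9.561 231.97 203.02
10.6439 193.43 171.03
10.739 190.38 168.41
10.739 261.01 232.4
11.271 230.93 206.25
11.271 240.12 200.37
12.2325 214.95 181.73
14.0583 150.56 129.51
16.1567 105.09 91.622
18.5682 73.184 64.436
21.3396 50.849 45.062
24.5248 35.269 31.353
28.1853 24.431 21.714
32.3922 16.914 14.977
37.2269 11.722 10.302
42.7834 8.1379 7.0659
49.1691 5.6637 4.8313
56.508 3.9569 3.2929
65.351 2.7629 2.2229
65.351 11.19 3.2417
74.6355 8.7977 3.2502
85.7754 6.1717 2.7184
98.5781 4.3221 2.1557
113.292 3.0333 1.6541
130.201 2.1354 1.2405
149.635 1.4993 0.90808
171.969 1.0623 0.65934
197.637 0.76143 0.47692
227.136 0.55341 0.34495
261.038 0.40891 0.25045
300 0.30787 0.18329
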