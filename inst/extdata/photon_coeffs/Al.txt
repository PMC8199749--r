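# element: Al
# Z: 13
# atomic_mass: 26.982
# density: 2.699
# columns: energy_keV mu_rho muen_rho (cm^2/g)
1 1185 1183
1.5 402.2 400.1
1.5596 362.1 360
1.5596 3957 3829
2 2263 2204
3 788 773.2
4 360.5 349.3
5 193.4 184.9
6 115.3 109.2
8 50.33 46.82
10 26.23 25.43
15 7.955 7.487
20 3.441 3.094
30 1.128 0.8778
40 0.5685 0.3601
50 0.3681 0.184
60 0.2778 0.1099
80 0.2018 0.05511
100 0.1704 0.03794
150 0.1378 0.02827
200 0.1223 0.02745
300 0.1042 0.02816
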