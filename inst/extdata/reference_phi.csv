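indicator_id,phi_reference
1,2797.489585
2,2882.96239
3,2970.58939
4,3194.823902
5,3585.256829
6,25.13292683
7,0
8,0
9,0
10,1459.994293
11,1252.504293
12,2083.364463
13,1426.177537
14,3178.441195
15,3615.334366
16,3688.969054
17,0
18,149.8918293
19,809.6299756
20,931.4538049
21,600.6179512
22,312.6046341
23,154.1476829
24,246.5156098
25,0
26,2.167195122
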