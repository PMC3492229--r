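age,value
40,0.14000000000000001
41,0.14130000000000001
42,0.1426
43,0.1439
44,0.14520000000000002
45,0.14650000000000002
46,0.14780000000000001
47,0.14910000000000001
48,0.15040000000000001
49,0.1517
50,0.15300000000000002
51,0.15430000000000002
52,0.15560000000000002
53,0.15690000000000001
54,0.15820000000000001
55,0.1595
56,0.1608
57,0.16210000000000002
58,0.16340000000000002
59,0.16470000000000001
60,0.16600000000000001
61,0.1673
62,0.16860000000000003
63,0.16990000000000002
64,0.17120000000000002
65,0.17250000000000001
66,0.17380000000000001
67,0.17510000000000001
68,0.1764
69,0.17770000000000002
70,0.17900000000000002
71,0.18030000000000002
72,0.18160000000000001
73,0.18290000000000001
74,0.1842
75,0.1855
76,0.18680000000000002
77,0.18810000000000002
78,0.18940000000000001
79,0.19070000000000001
80,0.192
81,0.19330000000000003
82,0.1946
83,0.19590000000000002
84,0.19720000000000001
85,0.19850000000000001
86,0.19980000000000001
87,0.2011
88,0.20240000000000002
89,0.20369999999999999
90,0.20500000000000002
91,0.20630000000000001
92,0.20760000000000001
93,0.20890000000000003
94,0.2102
95,0.21150000000000002
96,0.21280000000000002
97,0.21410000000000001
98,0.21540000000000001
99,0.2167
100,0.21800000000000003
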