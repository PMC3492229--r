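age,value
40,39.97421721730025
41,39.083353925150554
42,38.196977122737565
43,37.31530575992948
44,36.438566309208255
45,35.566992734698154
46,34.700826428774292
47,33.840316113521453
48,32.985717704285719
49,32.137294132558146
50,31.295315125452767
51,30.460056939095907
52,29.631802043332033
53,28.810838755277537
54,27.997460819421281
55,27.191966932182229
56,26.39466020909374
57,25.605847593093447
58,24.825839202759163
59,24.054947619747349
60,23.293487115161494
61,22.541772815104373
62,21.800119806249128
63,21.068842182898091
64,20.348252037682219
65,19.638658398783395
66,18.940366117331084
67,18.253674709426786
68,17.578877158075343
69,16.916258681141368
70,16.266095472289447
71,15.62865342269559
72,15.004186832119078
73,14.392937118682694
74,13.795131537408343
75,13.210981918176202
76,12.640683434300946
77,12.084413413330081
78,11.542330201949655
79,11.014572097015099
80,10.501256354694984
81,10.002478289510691
82,9.5183104746657001
83,9.0488020544783883
84,8.5939781789601799
85,8.1538395696193327
86,7.7283622244283352
87,7.317497268584348
88,6.9211709562395205
89,6.5392848268114951
90,6.171716017845136
91,5.8183177347388089
92,5.4789198760465139
93,5.1533298116243547
94,4.8413333097573883
95,4.5426956088133617
96,4.2571626292989642
97,3.9844623240786667
98,3.7243061690801955
99,3.476390806113463
100,3.2403998673706336
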