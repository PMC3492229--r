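age,value
40,0.002
41,0.0021618129115187215
42,0.0023367175322045264
43,0.0025257730658459544
44,0.0027301244126560057
45,0.0029510091026661101
46,0.0031897647900764364
47,0.0034478373539475228
48,0.0037267896542901497
49,0.004028310996579419
50,0.0043542273620091193
51,0.004706512465439708
52,0.0050872997080056871
53,0.005498895096766058
54,0.005943791209637928
55,0.0064246822901833757
56,0.006944480563662047
57,0.0075063338731577132
58,0.0081136447425813382
59,0.0087700909819941678
60,0.0094796479600344468
61,0.010246612678327291
62,0.01107562979366968
63,0.011971719745578277
64,0.012940309159537375
65,0.013987263710065936
66,0.015118923642618898
67,0.016342142169439602
68,0.017664326971884553
69,0.019093485060554211
70,0.020638271264897957
71,0.022308040645941118
72,0.024112905149539975
73,0.02606379484325089
74,0.028172524107657436
75,0.030451863183003147
76,0.032915615504408899
77,0.035578701294008482
78,0.038457247916227712
79,0.041568687543388751
80,0.044931862723092623
81,0.048567140486684202
82,0.052496535689828774
83,0.056743844332137611
84,0.061334787663211758
85,0.066297167947795207
86,0.071661036833334413
87,0.0774588773395605
88,0.08372580057220344
89,0.090499758352115475
90,0.097821773047463742
91,0.10573618600083058
92,0.11429092605567033
93,0.12353779980828979
94,0.13353280534308806
95,0.14433647135100194
96,0.15601422368482404
97,0.16863678157121123
98,0.18228058587880341
99,0.19702826203599719
100,0.21296912040175633
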