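age,value
40,35.02895323165486
41,34.248299831317496
42,33.471577891058686
43,32.698979274165012
44,31.930702435904145
45,31.166952396384978
46,30.407940685008402
47,29.653885254116734
48,28.905010359425628
49,28.161546404818996
50,27.423729749108094
51,26.69180247240363
52,25.966012099827037
53,25.246611280397843
54,24.533857419080505
55,23.828012260159685
56,23.129341420339877
57,22.438113870236524
58,21.754601363242564
59,21.079077811118811
60,20.41181860606935
61,19.753099889524453
62,19.103197768362637
63,18.462387479859149
64,17.830942507247304
65,17.20913364841844
66,16.597228040960228
67,15.995488147435843
68,15.404170705529941
69,14.82352564842285
70,14.253795001490751
71,13.69521176215593
72,13.147998770413626
73,12.612367578227103
74,12.088517326594941
75,11.57663363963894
76,11.076887545521448
77,10.58943443436141
78,10.114413063564131
79,9.6519446210957067
80,9.202131857206945
81,8.7650582949320484
82,8.3407875293462315
83,7.9293626250583813
84,7.5308056207383016
85,7.1451171486354976
86,6.7722761760454482
87,6.4122398745326761
88,6.0649436214470027
89,5.7303011368966708
90,5.4082047579055317
91,5.0985258500288531
92,4.8011153552984913
93,4.5158044741038159
94,4.2424054776224542
95,3.980712646898307
96,3.7305033349527004
97,3.4915391499658419
98,3.2635672615651199
99,3.0463218404087047
100,2.8395256569742666
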