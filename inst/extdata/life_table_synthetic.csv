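age,qx
40,0.0018299117221839
41,0.00200224234786434
42,0.0021908020867787
43,0.00239711930404096
44,0.00262286629745495
45,0.00286987285227231
46,0.00314014107246008
47,0.00343586160869232
48,0.00375943141460116
49,0.00411347317521008
50,0.00450085656502609
51,0.00492472150809732
52,0.00538850362857002
53,0.00589596209803353
54,0.00645121010536891
55,0.00705874819607384
56,0.00772350075129454
57,0.00845085590224436
58,0.00924670920353417
59,0.0101175114194074
60,0.0110703208102093
61,0.0121128603428977
62,0.0132535802893113
63,0.0145017267195867
64,0.0158674164458925
65,0.0173617190239367
66,0.0189967464769071
67,0.0207857514690993
68,0.0227432347249763
69,0.0248850625643404
70,0.0272285955062965
71,0.0297928289844008
72,0.0325985473135586
73,0.0356684921566434
74,0.0390275468563402
75,0.0427029381263076
76,0.0467244567364605
77,0.0511246989811318
78,0.0559393308873243
79,0.0612073773045868
80,0.0669715382197208
81,0.0732785348601992
82,0.0801794883916258
83,0.0877303342787573
84,0.095992275668678
85,0.105032279471009
86,0.114923619156117
87,0.125746468670954
88,0.137588552286501
89,0.150545855644119
90,0.164723403764192
91,0.180236112323169
92,0.197209719099015
93,0.215781803134871
94,0.236102899881716
95,0.258337721358799
96,0.282666491221801
97,0.309286405560079
98,0.338413231263459
99,0.370283054914061
100,0.405154196378769
101,0.4433093026129
102,0.485057638646326
103,0.530737594321584
104,0.580719427102246
105,0.6354082631833
106,0.695247381228959
107,0.76072180535412
108,0.832362236472278
109,0.910749353875323
110,0.996518521911515
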