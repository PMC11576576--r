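energy_keV,relative_fluence
10,0
11,0
12,0
13,0
14,0
15,5.618472e-08
16,7.520063e-07
17,5.515404e-06
18,2.604888e-05
19,8.864221e-05
20,0.0002353834
21,0.00051671
22,0.0009782876
23,0.0016488
24,0.00253356
25,0.003614909
26,0.004857467
27,0.00621541
28,0.00763949
29,0.00908254
30,0.01050306
31,0.01186707
32,0.0131486
33,0.01432934
34,0.01539769
35,0.01634771
36,0.01717789
37,0.01789017
38,0.01848891
39,0.01898021
40,0.01937118
41,0.01966957
42,0.01988329
43,0.02002022
44,0.02008801
45,0.02009393
46,0.02004479
47,0.01994694
48,0.01980621
49,0.01962792
50,0.01941693
51,0.0191776
52,0.01891388
53,0.0186293
54,0.01832701
55,0.01800984
56,0.01768029
57,0.01734058
58,0.01699268
59,0.01663833
60,0.01627907
61,0.01591625
62,0.01555104
63,0.0151845
64,0.01481754
65,0.01445093
66,0.01408538
67,0.01372149
68,0.01335976
69,0.01300065
70,0.01264453
71,0.01229174
72,0.01194253
73,0.01159715
74,0.01125579
75,0.0109186
76,0.0105857
77,0.0102572
78,0.009933177
79,0.009613679
80,0.009298747
81,0.008988402
82,0.008682651
83,0.00838149
84,0.008084903
85,0.007792868
86,0.007505351
87,0.007222315
88,0.006943715
89,0.006669501
90,0.00639962
91,0.006134016
92,0.005872628
93,0.005615395
94,0.005362252
95,0.005113135
96,0.004867976
97,0.004626708
98,0.004389264
99,0.004155576
100,0.003925575
101,0.003699193
102,0.003476363
103,0.003257017
104,0.00304109
105,0.002828514
106,0.002619225
107,0.002413158
108,0.00221025
109,0.002010438
110,0.001813661
111,0.001619858
112,0.001428969
113,0.001240937
114,0.001055703
115,0.0008732114
116,0.0006934073
117,0.0005162365
118,0.0003416461
119,0.0001695841
120,0
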