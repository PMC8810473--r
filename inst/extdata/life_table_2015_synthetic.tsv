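age	annual_death_probability
18	0.00065
19	0.000721
20	8e-04
21	0.000828
22	0.000857
23	0.000887
24	0.000918
25	0.00095
26	0.000978
27	0.001007
28	0.001037
29	0.001068
30	0.0011
31	0.001146
32	0.001194
33	0.001244
34	0.001296
35	0.00135
36	0.00143
37	0.001515
38	0.001604
39	0.001699
40	0.0018
41	0.001952
42	0.002117
43	0.002296
44	0.00249
45	0.0027
46	0.002921
47	0.00316
48	0.003418
49	0.003698
50	0.004
51	0.004338
52	0.004704
53	0.005102
54	0.005533
55	0.006
56	0.006492
57	0.007025
58	0.007601
59	0.008225
60	0.0089
61	0.009586
62	0.010325
63	0.01112
64	0.011977
65	0.0129
66	0.013997
67	0.015187
68	0.016478
69	0.01788
70	0.0194
71	0.021223
72	0.023218
73	0.025401
74	0.027788
75	0.0304
76	0.033621
77	0.037184
78	0.041124
79	0.045481
80	0.0503
81	0.05619
82	0.062769
83	0.070118
84	0.078329
85	0.0875
86	0.09791
87	0.109559
88	0.122594
89	0.137179
90	0.1535
91	0.169053
92	0.186181
93	0.205045
94	0.22582
95	0.2487
96	0.267346
97	0.287391
98	0.308938
99	0.332101
100	0.357
101	0.37846
102	0.40121
103	0.425328
104	0.450896
105	0.478
106	0.496853
107	0.51645
108	0.536819
109	0.557992
110	0.58
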