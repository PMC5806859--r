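sample_id,material,histology,cytology_class,total_cells,wbc,hfbf,hfbf_percent,rule1,rule2,micro_diff,micro_count
1,PE,Adenocarcinoma,V,1828,998,830,83.2,+,+,+,+
2,PE,Adenocarcinoma,V,1241,771,470,61.0,+,+,+,+
3,PE,Adenocarcinoma,V,2460,1623,837,51.6,+,+,-,+
4,PE,Adenocarcinoma,V,3597,2526,1071,42.4,+,+,+,+
5,PE,Adenocarcinoma,V,3424,2723,701,25.7,+,+,+,+
6,PE,Lung Adenocarcinoma,V,1469,342,1127,329.5,+,-,+,+
7,PE,Malignant Lymphoma,V,1333,612,721,117.8,+,-,+,+
8,PE,Adenocarcinoma,V,1528,1018,510,50.1,+,-,-,+
9,PE,Adenocarcinoma,V,353,271,82,30.3,+,-,+,+
10,AF,Adenocarcinoma,V,124,100,24,24.0,+,-,+,+
11,PE,Small cell carcinoma,V,2124,1733,391,22.6,+,-,+,+
12,AF,Adenocarcinoma,V,1404,1160,244,21.0,+,-,+,+
13,PE,Adenocarcinoma,V,385,344,41,11.9,+,-,+,+
14,PE,Lung Adenocarcinoma,V,1391,1320,71,5.4,+,-,+,+
15,PE,Adenocarcinoma,V,218,124,94,75.8,-,+,+,+
16,PE,Malignant Mesothelioma,V,426,358,68,19.0,-,+,+,+
17,PE,Adenocarcinoma,V,609,494,115,23.3,-,-,-,-
18,PE,Adenocarcinoma,V,297,277,20,7.2,-,-,+,-
19,PE,Adenocarcinoma,IIIb,1682,1590,92,5.8,-,-,-,-
20,PE,Adenocarcinoma,V,2773,2647,126,4.8,-,-,+,+
21,PE,Adenocarcinoma,V,386,376,10,2.7,-,-,-,-
22,PE,Lung Adenocarcinoma,V,3888,3806,82,2.2,-,-,+,-
23,PE,Malignant Lymphoma,V,2927,2885,42,1.5,-,-,-,-
24,PE,Adenocarcinoma,V,3786,3737,49,1.3,-,-,-,-
25,AF,Adenocarcinoma,V,207,182,25,13.7,-,-,-,-
26,CSF,unknown,V,909,373,536,143.7,-,+,+,+
27,CSF,Medullobrastoma,V,53,50,3,6.0,-,-,+,-
28,PE,N/D,II,5692,4977,715,14.4,+,+,+,+
29,PE,N/D,II,5458,5240,218,4.2,+,-,-,-
30,PE,N/D,II,2785,2558,227,8.9,+,-,-,-
31,PE,N/D,II,1203,985,218,22.1,-,+,+,+
32,PE,N/D,IIb,2106,1825,281,15.4,-,+,-,-
33,PE,N/D,II,106,84,22,26.2,-,+,-,-
34,PE,N/D,II,217,193,24,12.4,-,+,-,-
35,PE,N/D,II,261,219,42,19.2,-,+,-,-
36,PE,N/D,III,89,85,4,4.7,-,-,-,+
37,PE,N/D,II,949,856,93,10.9,-,-,-,+
38,PE,N/D,II,3596,3500,96,2.7,-,-,-,+
39,PE,N/D,III,949,816,133,16.3,-,-,-,-
40,PE,N/D,III,48,45,3,6.7,-,-,-,-
41,PE,N/D,III,1008,994,14,1.4,-,-,-,-
42,PE,N/D,III,307,287,20,7.0,-,-,-,-
43,PE,N/D,III,242,219,23,10.5,-,-,-,-
44,PE,N/D,III,6760,6647,113,1.7,-,-,-,-
45,PE,N/D,III,7037,6668,369,5.5,-,-,-,-
46,PE,N/D,IIb,208,174,34,19.5,-,-,-,-
47,PE,N/D,IIb,1114,1031,83,8.1,-,-,-,-
48,PE,N/D,II,59,58,1,1.7,-,-,-,-
49,PE,N/D,II,36,34,2,5.9,-,-,-,-
50,PE,N/D,II,359,357,2,0.6,-,-,-,-
51,PE,N/D,II,609,606,3,0.5,-,-,-,-
52,PE,N/D,II,706,702,4,0.6,-,-,-,-
53,PE,N/D,II,1914,1907,7,0.4,-,-,-,-
54,PE,N/D,II,5216,5207,9,0.2,-,-,-,-
55,PE,N/D,II,193,173,20,11.6,-,-,-,-
56,PE,N/D,II,239,217,22,10.1,-,-,-,-
57,PE,N/D,II,842,817,25,3.1,-,-,-,-
58,PE,N/D,II,1753,1728,25,1.4,-,-,-,-
59,PE,N/D,II,208,178,30,16.9,-,-,-,-
60,PE,N/D,II,273,243,30,12.3,-,-,-,-
61,PE,N/D,II,6651,6620,31,0.5,-,-,-,-
62,PE,N/D,II,1014,972,42,4.3,-,-,-,-
63,PE,N/D,II,6632,6578,54,0.8,-,-,-,-
64,PE,N/D,II,509,452,57,12.6,-,-,-,-
65,AF,N/D,II,1271,1197,74,6.2,-,-,-,-
66,PE,N/D,II,777,699,78,11.2,-,-,-,-
67,PE,N/D,II,1945,1838,107,5.8,-,-,-,-
68,PE,N/D,II,2354,2234,120,5.4,-,-,-,-
69,PE,N/D,II,2232,2107,125,5.9,-,-,-,-
70,AF,N/D,II,548,399,149,37.3,-,-,-,-
71,PE,N/D,II,1736,1470,266,18.1,-,-,-,-
72,PE,N/D,II,3891,3539,352,9.9,-,-,-,-
73,PE,N/D,II,3148,2746,402,14.6,-,-,-,-
74,AF,N/D,II,268,253,15,5.9,-,-,-,-
75,PE,N/D,II,1166,1143,23,2.0,-,-,-,-
76,PE,N/D,II,1127,1096,31,2.8,-,-,-,-
77,CSF,N/D,III,2,2,0,0.0,-,-,-,-
78,CSF,N/D,III,8,8,0,0.0,-,-,-,-
79,CSF,N/D,III,112,106,6,5.7,-,-,-,-
80,CSF,N/D,Negative,1,1,0,0.0,-,-,-,-
81,CSF,N/D,Negative,1,1,0,0.0,-,-,-,-
82,CSF,N/D,Negative,1,1,0,0.0,-,-,-,-
83,CSF,N/D,Negative,2,2,0,0.0,-,-,-,-
84,CSF,N/D,Negative,2,2,0,0.0,-,-,-,-
85,CSF,N/D,Negative,2,2,0,0.0,-,-,-,-
86,CSF,N/D,Negative,11,10,1,10.0,-,-,-,-
87,CSF,N/D,Negative,7,7,0,0.0,-,-,-,-
88,CSF,N/D,Negative,246,241,5,2.1,-,-,-,-
89,CSF,N/D,Negative,115,115,0,0.0,-,-,-,-
90,CSF,N/D,Negative,23,22,1,4.5,-,-,-,-
91,CSF,N/D,Negative,5,5,0,0.0,-,-,-,-
92,CSF,N/D,Negative,10,9,1,11.1,-,-,-,-
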