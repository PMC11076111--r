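"id","twin","qualification","word_definitions","recall_digits","similarities","matrices","numeracy"
1,0,"Degree",19,23,10,18,19
2,0,"A-level",21,14,11,9,16
3,0,"O-level",19,29,7,11,19
4,0,"O-level",18,15,4,10,13
5,0,"A-level",15,27,9,12,0
6,0,"Degree",26,24,12,14,23
7,0,"O-level",20,32,18,9,18
8,1,"O-level",18,19,6,15,19
9,0,"O-level",13,15,8,6,9
10,0,"O-level",13,21,8,5,11
11,0,"O-level",8,14,6,7,10
12,0,"A-level",17,26,13,18,23
13,0,"A-level",22,22,15,10,23
14,0,"A-level",15,24,8,17,18
15,0,"O-level",2,13,1,1,2
16,1,"O-level",18,14,6,13,14
17,0,NA,6,11,8,6,5
18,0,"Degree",16,19,17,14,23
19,0,"O-level",10,16,8,11,11
20,0,"O-level",7,11,4,6,6
21,0,"Higher degree",14,33,12,12,23
22,0,"O-level",19,24,14,11,18
23,0,"A-level",26,24,10,18,23
24,1,"Degree",16,15,6,16,12
25,0,"Degree",17,16,14,17,15
26,0,"O-level",7,16,5,9,12
27,0,"Degree",16,19,11,8,13
28,0,"Degree",15,23,13,19,18
29,0,"O-level",3,16,7,6,10
30,0,"Degree",16,25,8,4,19
31,0,"O-level",12,15,6,6,6
32,1,"O-level",14,22,14,8,13
33,0,"Degree",13,21,11,10,16
34,0,"Higher degree",21,27,16,15,20
35,0,"O-level",14,18,6,9,15
36,0,"O-level",11,16,17,15,23
37,0,"A-level",16,17,13,14,23
38,0,"O-level",10,21,10,11,20
39,0,"O-level",13,10,8,15,16
40,1,"A-level",19,25,12,13,20
41,0,"A-level",14,18,7,7,15
42,0,"O-level",15,18,11,10,21
43,0,"A-level",18,23,10,14,23
44,0,"Higher degree",16,19,16,21,23
45,0,"O-level",12,10,2,4,14
46,0,"O-level",13,20,6,8,16
47,0,"A-level",24,26,9,10,19
48,1,"O-level",14,27,13,13,15
49,0,"Higher degree",16,20,16,19,23
50,0,"Higher degree",25,27,23,17,23
51,0,"O-level",12,17,6,9,18
52,0,"O-level",13,16,10,7,9
53,0,"O-level",3,25,8,4,11
54,0,NA,18,13,6,6,11
55,0,"O-level",13,15,4,11,17
56,1,"O-level",12,16,3,7,8
57,0,"Higher degree",15,27,13,13,23
58,0,"O-level",16,20,9,16,15
59,0,"Higher degree",16,22,7,10,20
60,0,"O-level",16,22,10,11,16
61,0,"Higher degree",20,25,10,18,15
62,0,"Degree",21,21,9,15,16
63,0,"Degree",17,27,16,24,23
64,1,"O-level",20,17,12,14,22
65,0,"Degree",23,22,17,15,23
66,0,"A-level",21,19,14,13,11
67,0,"O-level",11,13,7,6,9
68,0,"A-level",17,24,9,18,19
69,0,"O-level",17,22,10,9,19
70,0,"O-level",9,16,6,5,7
71,0,"A-level",19,29,11,12,19
72,1,"O-level",8,11,3,11,7
73,0,"Degree",16,12,10,17,17
74,0,"Degree",16,23,9,9,23
75,0,"Degree",13,23,16,13,21
76,0,"A-level",12,24,10,13,13
77,0,"Higher degree",12,16,17,9,20
78,0,"Degree",20,10,12,10,13
79,0,"Degree",18,22,7,10,11
80,1,"O-level",16,28,9,11,14
81,0,"O-level",10,13,7,5,14
82,0,"Degree",11,18,19,15,16
83,0,"A-level",23,21,17,16,12
84,0,"O-level",4,14,5,6,5
85,0,"Degree",17,19,12,12,12
86,0,"A-level",19,23,10,13,16
87,0,"O-level",11,19,11,12,15
88,1,"O-level",15,16,10,9,0
89,0,"A-level",11,16,8,9,13
90,0,"Degree",17,23,14,13,14
91,0,"O-level",9,13,10,5,16
92,0,"O-level",10,19,4,15,18
93,0,"O-level",17,19,9,9,14
94,0,"O-level",12,13,11,14,23
95,0,"Degree",13,20,10,9,14
96,1,"O-level",10,14,1,7,15
97,0,"O-level",4,14,10,11,11
98,0,"O-level",12,23,8,9,16
99,0,"O-level",17,24,12,12,14
100,0,"Higher degree",16,25,17,10,13
101,0,"Higher degree",21,25,18,16,20
102,0,"Higher degree",19,14,16,6,14
103,0,"Degree",22,23,17,18,18
104,1,"O-level",20,17,10,15,23
105,0,"O-level",7,16,5,11,8
106,0,"A-level",18,23,10,17,22
107,0,"O-level",11,21,8,17,14
108,0,"Higher degree",16,21,18,15,17
109,0,"O-level",15,21,4,5,11
110,0,"O-level",11,16,10,11,13
111,0,"O-level",7,25,7,11,10
112,1,"Higher degree",20,19,10,15,16
113,0,"O-level",12,16,8,10,8
114,0,"O-level",17,22,11,17,13
115,0,"O-level",9,20,11,6,8
116,0,"O-level",5,16,3,8,7
117,0,"Higher degree",20,22,10,12,23
118,0,"A-level",20,17,19,12,17
119,0,"O-level",13,21,9,14,16
120,1,"A-level",20,17,10,10,15
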