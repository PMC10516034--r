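config_id,temporal_order_code,spatial_order_code,class_label
1,---,---,XIII
2,---,--+,XIII
3,---,--0,X
4,---,-++,XIII
5,---,-0+,IX
6,---,+--,XIII
7,---,++-,XIII
8,---,+++,XIII
9,---,++0,X
10,---,+0-,IX
11,---,0--,VIII
12,---,0++,VIII
13,---,000,II
14,--+,---,XIII
15,--+,--+,XIII
16,--+,--0,X
17,--+,-++,XIII
18,--+,-0+,VIII
19,--+,+--,XIII
20,--+,++-,XIII
21,--+,+++,XIII
22,--+,++0,X
23,--+,+0-,VIII
24,--+,0--,IX
25,--+,0++,IX
26,--+,000,II
27,--0,---,XII
28,--0,--+,XII
29,--0,--0,V
30,--0,-++,XII
31,--0,-0+,VI
32,--0,+--,XII
33,--0,++-,XII
34,--0,+++,XII
35,--0,++0,V
36,--0,+0-,VI
37,--0,0--,VI
38,--0,0++,VI
39,--0,000,I
40,-++,---,XIII
41,-++,--+,XIII
42,-++,--0,IX
43,-++,-++,XIII
44,-++,-0+,VIII
45,-++,+--,XIII
46,-++,++-,XIII
47,-++,+++,XIII
48,-++,++0,IX
49,-++,+0-,VIII
50,-++,0--,X
51,-++,0++,X
52,-++,000,II
53,-0+,---,XI
54,-0+,--+,XI
55,-0+,--0,VII
56,-0+,-++,XI
57,-0+,-0+,V
58,-0+,+--,XI
59,-0+,++-,XI
60,-0+,+++,XI
61,-0+,++0,VII
62,-0+,+0-,V
63,-0+,0--,VII
64,-0+,0++,VII
65,-0+,000,I
66,+--,---,XIII
67,+--,--+,XIII
68,+--,--0,IX
69,+--,-++,XIII
70,+--,-0+,X
71,+--,+--,XIII
72,+--,++-,XIII
73,+--,+++,XIII
74,+--,++0,IX
75,+--,+0-,X
76,+--,0--,VIII
77,+--,0++,VIII
78,+--,000,II
79,++-,---,XIII
80,++-,--+,XIII
81,++-,--0,VIII
82,++-,-++,XIII
83,++-,-0+,X
84,++-,+--,XIII
85,++-,++-,XIII
86,++-,+++,XIII
87,++-,++0,VIII
88,++-,+0-,X
89,++-,0--,IX
90,++-,0++,IX
91,++-,000,II
92,+++,---,XIII
93,+++,--+,XIII
94,+++,--0,VIII
95,+++,-++,XIII
96,+++,-0+,IX
97,+++,+--,XIII
98,+++,++-,XIII
99,+++,+++,XIII
100,+++,++0,VIII
101,+++,+0-,IX
102,+++,0--,X
103,+++,0++,X
104,+++,000,II
105,++0,---,XI
106,++0,--+,XI
107,++0,--0,V
108,++0,-++,XI
109,++0,-0+,VII
110,++0,+--,XI
111,++0,++-,XI
112,++0,+++,XI
113,++0,++0,V
114,++0,+0-,VII
115,++0,0--,VII
116,++0,0++,VII
117,++0,000,I
118,+0-,---,XII
119,+0-,--+,XII
120,+0-,--0,VI
121,+0-,-++,XII
122,+0-,-0+,V
123,+0-,+--,XII
124,+0-,++-,XII
125,+0-,+++,XII
126,+0-,++0,VI
127,+0-,+0-,V
128,+0-,0--,VI
129,+0-,0++,VI
130,+0-,000,I
131,0--,---,XI
132,0--,--+,XI
133,0--,--0,VII
134,0--,-++,XI
135,0--,-0+,VII
136,0--,+--,XI
137,0--,++-,XI
138,0--,+++,XI
139,0--,++0,VII
140,0--,+0-,VII
141,0--,0--,V
142,0--,0++,V
143,0--,000,I
144,0++,---,XII
145,0++,--+,XII
146,0++,--0,VI
147,0++,-++,XII
148,0++,-0+,VI
149,0++,+--,XII
150,0++,++-,XII
151,0++,+++,XII
152,0++,++0,VI
153,0++,+0-,VI
154,0++,0--,V
155,0++,0++,V
156,0++,000,I
157,000,---,IV
158,000,--+,IV
159,000,--0,III
160,000,-++,IV
161,000,-0+,III
162,000,+--,IV
163,000,++-,IV
164,000,+++,IV
165,000,++0,III
166,000,+0-,III
167,000,0--,III
168,000,0++,III
169,000,000,0
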