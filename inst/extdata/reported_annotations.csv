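no,rt_min,calcd_mz,obs_mz,name,first_report,calcd_consistent
1,3.4,692.3277,692.3285,8-dhbtn-BMA,TRUE,TRUE
2,3.4,762.2968,762.2968,8-act-10-OH-BMA,TRUE,TRUE
3,3.6,902.3805,902.3777,8-gvl-BMA,TRUE,TRUE
4,3.8,746.3018,746.3002,8-act-BMA,TRUE,TRUE
5,4.0,692.3277,692.3258,8-hbtn-10-OH-BMA,TRUE,TRUE
6,4.2,914.3805,914.3784,8-gcf-BMA,TRUE,TRUE
7,4.5,928.3961,928.3946,8-gfr-BMA,TRUE,TRUE
8,4.6,730.3069,730.3041,8-act-BHA,TRUE,TRUE
9,4.7,734.3382,734.3324,8-adp-10-OH-BMA,TRUE,TRUE
10,4.7,734.3382,734.3324,8-hadp-BMA,TRUE,TRUE
11,4.8,676.3328,676.3321,8-hbtn-BMA,TRUE,TRUE
12,5.0,760.3175,760.3189,8-act-BA,TRUE,TRUE
13,5.3,760.3175,760.3176,8-dohpnd-BMA,TRUE,TRUE
14,5.6,672.3015,672.302,8-fmr-BHA,TRUE,TRUE
15,5.8,660.3384,660.338,8-hbtn-BHA,TRUE,FALSE
16,5.8,744.3226,744.3244,8-act-DBA,TRUE,TRUE
17,5.9,942.4118,942.4084,8-gfr-BA,TRUE,TRUE
18,6.2,704.3277,704.3249,8-scn-BA,FALSE,TRUE
19,6.3,674.3173,674.3172,8-scn-BHA,TRUE,TRUE
20,6.6,732.359,732.3601,8-adp-BA,FALSE,TRUE
21,6.7,702.3484,702.3473,8-adp-BHA,TRUE,TRUE
22,6.8,674.3535,674.3499,8-hbte-DBA,TRUE,FALSE
23,6.9,686.3171,686.317,8-fmr-DBA,TRUE,TRUE
24,7.2,688.3691,688.3682,8-hvlr-DBA,TRUE,TRUE
25,7.6,686.3171,686.3173,8-gtn-BHA,TRUE,TRUE
26,7.7,716.3641,716.3633,8-adp-DBA,TRUE,TRUE
27,8.2,718.3433,718.3443,8-gtr-BA,FALSE,TRUE
28,8.7,658.3222,658.3244,8-bte-BMA,TRUE,TRUE
29,9.8,760.3903,760.3903,8-azl-BMA,TRUE,TRUE
30,10.3,744.4059,774.4051,8-sbc-BMA,TRUE,FALSE
31,10.8,644.3429,644.3423,8-btn-BHA,TRUE,TRUE
32,10.8,674.3535,674.3529,8-btn-BA,TRUE,TRUE
33,10.8,674.3535,674.3529,8-vlr-BMA,TRUE,TRUE
34,10.9,744.3954,744.396,8-hnne-BMA,TRUE,TRUE
35,11.4,902.5266,902.5268,8-thode-BMA,TRUE,FALSE
36,11.5,758.411,758.4119,8-azl-DBA,TRUE,TRUE
37,11.6,758.411,758.4107,8-hnne-BA,TRUE,TRUE
38,11.8,688.3691,688.3678,8-vlr-BA,FALSE,TRUE
39,12.0,658.3586,658.3558,8-btn-DBA,FALSE,TRUE
40,12.0,702.312,702.3845,8-hxn-BA,FALSE,FALSE
41,12.0,658.3586,658.3599,8-vlr-BHA,TRUE,TRUE
42,12.2,916.5417,916.5399,8-thode-BA,TRUE,TRUE
43,12.3,886.5311,886.5662,8-thode-BHA,TRUE,TRUE
44,12.5,728.4004,728.3993,8-hnne-BHA,TRUE,TRUE
45,13.0,900.5468,900.5474,8-thode-DBA,TRUE,TRUE
46,13.2,790.4372,790.4367,8-dhudn-BMA,FALSE,TRUE
47,13.3,672.3742,672.3752,8-vlr-DBA,TRUE,TRUE
48,13.3,916.5417,916.5401,8-thnde-BMA,TRUE,TRUE
49,13.5,800.4216,800.4234,8-dded-BMA,TRUE,TRUE
50,13.6,774.4423,774.44,8-dhudn-BHA,FALSE,TRUE
51,13.6,782.5202,782.5161,8-pal-DMBHA,TRUE,TRUE
52,15.1,716.4004,716.3982,8-otn-BMA,TRUE,TRUE
53,15.2,884.5155,884.5174,8-dhodd-BMA,TRUE,TRUE
54,15.9,730.4161,730.4154,8-nnn-BMA,TRUE,TRUE
55,16.2,898.5311,898.5307,8-dhodd-BA,TRUE,TRUE
56,16.3,886.5311,886.5318,8-dhode-BMA,TRUE,TRUE
57,16.8,900.5468,900.5438,8-dhode-BA,TRUE,TRUE
58,17.0,866.5049,866.5054,8-hodt-BMA,TRUE,TRUE
59,17.1,868.5206,868.5191,8-dhodd-BHA,TRUE,TRUE
60,17.3,888.5468,888.5438,8-dhstr-BMA,TRUE,TRUE
61,17.4,870.5362,870.5335,8-dhode-BHA,TRUE,TRUE
62,18.1,884.5313,884.5292,8-hodd-10-OH-BMA,TRUE,FALSE
63,18.1,884.5519,884.5486,8-dhode-DBA,TRUE,TRUE
64,18.4,880.5206,880.5199,8-hodt-BA,TRUE,TRUE
65,18.4,850.5,850.5096,8-hodt-BHA,TRUE,FALSE
66,18.5,872.5519,872.5518,8-dhstr-BHA,TRUE,TRUE
67,18.8,868.5206,868.5196,8-hodd-BMA,TRUE,TRUE
68,18.8,910.5311,910.5304,8-dhecte-BMA,TRUE,TRUE
69,19.4,882.5368,882.5349,8-hodd-BA,TRUE,FALSE
70,19.8,924.5548,924.5455,8-dhhctte-BA,TRUE,FALSE
71,20.1,852.5256,852.5264,8-hodd-BHA,TRUE,TRUE
72,20.1,870.5362,870.5359,8-hode-BMA,TRUE,TRUE
73,21.0,864.5256,864.5255,8-hodt-DBA,TRUE,TRUE
74,21.2,866.5413,866.541,8-hodd-DBA,TRUE,TRUE
75,21.8,884.5519,884.5494,8-hode-BA,TRUE,TRUE
76,22.4,866.5049,866.5061,8-linolen-10-OH-BMA,FALSE,TRUE
77,22.5,880.5206,880.5193,8-linolen-10-OH-BA,FALSE,TRUE
78,22.5,824.4943,824.4888,8-pmde-BMA,FALSE,TRUE
79,22.7,854.5413,854.5409,8-hode-BHA,FALSE,TRUE
80,22.9,850.51,850.5105,8-linolen-BMA,FALSE,TRUE
81,22.9,812.4943,812.4874,8-ptde-BMA,FALSE,TRUE
82,23.0,772.463,772.4618,8-laur-BMA,TRUE,TRUE
83,23.1,864.5256,864.5252,8-linolen-BA,FALSE,TRUE
84,23.2,826.51,826.5052,8-pme-BMA,FALSE,TRUE
85,23.3,818.5202,818.5209,8-linolen-3-DMDBA,TRUE,TRUE
86,23.4,848.5307,848.531,8-linolen-DBA,FALSE,TRUE
87,23.6,868.5206,868.5195,8-lino-10-OH-BMA,FALSE,TRUE
88,23.8,838.51,838.5105,8-hpdde-BMA,TRUE,TRUE
89,23.8,840.5256,840.5184,8-pme-BA,FALSE,TRUE
90,23.9,868.5569,868.5559,8-hode-DBA,TRUE,TRUE
91,23.9,882.5362,882.5317,8-lino-10-OH-BA,FALSE,TRUE
92,24.1,822.5151,822.514,8-hpdde-BHA,TRUE,TRUE
93,24.2,834.5151,834.5136,8-linolen-BHA,FALSE,TRUE
94,24.2,844.5206,844.5218,8-pal-10-OH-BMA,FALSE,TRUE
95,24.3,806.5202,806.519,8-lino-DMBHA,TRUE,TRUE
96,24.3,784.4994,784.4973,8-myr-BHA,FALSE,TRUE
97,24.4,820.5358,820.5348,8-lino-13-DMDBA,TRUE,TRUE
98,24.5,840.5256,840.5249,8-hpde-BMA,FALSE,TRUE
99,24.6,814.51,814.5087,8-ptdn-BMA,FALSE,TRUE
100,24.6,796.4994,796.496,8-ptde-BHA,FALSE,TRUE
101,24.7,854.5413,854.5778,8-hstr-DMA,TRUE,FALSE
102,24.8,852.5256,852.5254,8-lino-BMA,FALSE,TRUE
103,24.9,820.5358,820.5359,8-lino-3-DMDBA,TRUE,TRUE
104,25.0,832.5358,832.5355,"8-linolen-3,13-DDBA",TRUE,TRUE
105,25.0,802.5252,802.5237,8-linolen-DMDDBA,TRUE,TRUE
106,25.1,836.5307,836.5293,8-lino-BHA,FALSE,TRUE
107,25.1,810.5151,810.5145,8-pme-BHA,FALSE,TRUE
108,25.3,866.5413,866.5408,8-lino-BA,FALSE,TRUE
109,25.3,870.5362,870.5372,8-ole-10-OH-BMA,FALSE,TRUE
110,25.5,808.5358,808.5306,8-ole-DMBHA,TRUE,TRUE
111,25.5,828.5256,828.5264,8-ptdn-BA,FALSE,TRUE
112,25.7,858.5362,858.5352,8-pal-10-OH-BA,FALSE,TRUE
113,25.9,798.5151,798.5128,8-ptdn-BHA,FALSE,TRUE
114,25.9,824.5307,824.5305,8-pme-DBA,TRUE,TRUE
115,26.0,822.5515,822.5527,8-ole-13-DMDBA,TRUE,TRUE
116,26.0,796.5358,796.5371,8-pal-DMDBA,TRUE,TRUE
117,26.1,822.5515,822.5511,8-ole-3-DMDBA,TRUE,TRUE
118,26.1,828.5256,828.5251,8-pal-BMA,FALSE,TRUE
119,26.1,796.5358,796.5368,8-pal-13-DMDBA,TRUE,TRUE
120,26.2,804.5409,804.5387,8-lino-DMDDBA,TRUE,TRUE
121,26.2,884.5519,884.5494,8-ole-10-OH-BA,FALSE,TRUE
122,26.3,854.5413,854.5403,8-ole-BMA,FALSE,TRUE
123,26.6,850.5464,850.5459,8-lino-DBA,FALSE,TRUE
124,26.8,880.5569,880.554,8-ecde-BMA,FALSE,TRUE
125,26.9,834.5515,834.5494,"8-lino-3,13-DDBA",FALSE,TRUE
126,26.9,842.5413,842.5396,8-pal-BA,FALSE,TRUE
127,26.9,812.5307,812.5292,8-ptdn-DBA,FALSE,TRUE
128,27.0,894.5362,894.5336,3-Acetyl-8-lino-BMA,FALSE,TRUE
129,27.1,868.5569,868.5576,8-ole-BA,FALSE,TRUE
130,27.2,838.5464,838.5443,8-ole-BHA,FALSE,TRUE
131,27.4,806.5565,806.5512,8-ole-DMDDBA,TRUE,TRUE
132,27.5,812.5307,812.53,8-pal-BHA,FALSE,TRUE
133,27.6,856.5569,856.5553,8-str-BMA,FALSE,TRUE
134,27.7,836.5619,836.5712,"8-ole-3,13-DDBA",TRUE,FALSE
135,28.0,826.5464,826.5465,8-pal-DBA,FALSE,TRUE
136,28.2,926.6352,926.6308,8-tcn-BMA,TRUE,TRUE
137,28.3,780.5409,780.5384,8-pal-DMDDBA,TRUE,TRUE
138,28.4,842.5413,842.5399,8-hpdn-BMA,FALSE,TRUE
139,28.5,852.562,852.562,8-ole-DBA,FALSE,TRUE
140,28.9,912.6195,912.6194,8-dcn-BMA,TRUE,TRUE
141,29.0,810.5515,810.549,"8-pal-3,13-DDBA",FALSE,TRUE
142,29.7,870.5726,870.5569,8-str-BA,FALSE,TRUE
143,29.7,954.6665,954.6648,8-ttcn-BA,FALSE,TRUE
144,30.5,840.562,840.5583,8-hpdn-DBA,FALSE,TRUE
145,30.5,840.562,840.5636,8-str-BHA,FALSE,TRUE
146,30.5,940.6508,940.6506,8-ttcn-BMA,FALSE,TRUE
147,30.9,926.6279,926.6308,8-dcn-BA,FALSE,FALSE
148,31.6,896.6246,896.6225,8-dcn-BHA,FALSE,TRUE
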