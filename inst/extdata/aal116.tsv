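region_id	name	hemisphere	homotopic_partner
1	Precentral_L	left	2
2	Precentral_R	right	1
3	Frontal_Sup_L	left	4
4	Frontal_Sup_R	right	3
5	Frontal_Sup_Orb_L	left	6
6	Frontal_Sup_Orb_R	right	5
7	Frontal_Mid_L	left	8
8	Frontal_Mid_R	right	7
9	Frontal_Mid_Orb_L	left	10
10	Frontal_Mid_Orb_R	right	9
11	Frontal_Inf_Oper_L	left	12
12	Frontal_Inf_Oper_R	right	11
13	Frontal_Inf_Tri_L	left	14
14	Frontal_Inf_Tri_R	right	13
15	Frontal_Inf_Orb_L	left	16
16	Frontal_Inf_Orb_R	right	15
17	Rolandic_Oper_L	left	18
18	Rolandic_Oper_R	right	17
19	Supp_Motor_Area_L	left	20
20	Supp_Motor_Area_R	right	19
21	Olfactory_L	left	22
22	Olfactory_R	right	21
23	Frontal_Sup_Medial_L	left	24
24	Frontal_Sup_Medial_R	right	23
25	Frontal_Med_Orb_L	left	26
26	Frontal_Med_Orb_R	right	25
27	Rectus_L	left	28
28	Rectus_R	right	27
29	Insula_L	left	30
30	Insula_R	right	29
31	Cingulum_Ant_L	left	32
32	Cingulum_Ant_R	right	31
33	Cingulum_Mid_L	left	34
34	Cingulum_Mid_R	right	33
35	Cingulum_Post_L	left	36
36	Cingulum_Post_R	right	35
37	Hippocampus_L	left	38
38	Hippocampus_R	right	37
39	ParaHippocampal_L	left	40
40	ParaHippocampal_R	right	39
41	Amygdala_L	left	42
42	Amygdala_R	right	41
43	Calcarine_L	left	44
44	Calcarine_R	right	43
45	Cuneus_L	left	46
46	Cuneus_R	right	45
47	Lingual_L	left	48
48	Lingual_R	right	47
49	Occipital_Sup_L	left	50
50	Occipital_Sup_R	right	49
51	Occipital_Mid_L	left	52
52	Occipital_Mid_R	right	51
53	Occipital_Inf_L	left	54
54	Occipital_Inf_R	right	53
55	Fusiform_L	left	56
56	Fusiform_R	right	55
57	Postcentral_L	left	58
58	Postcentral_R	right	57
59	Parietal_Sup_L	left	60
60	Parietal_Sup_R	right	59
61	Parietal_Inf_L	left	62
62	Parietal_Inf_R	right	61
63	SupraMarginal_L	left	64
64	SupraMarginal_R	right	63
65	Angular_L	left	66
66	Angular_R	right	65
67	Precuneus_L	left	68
68	Precuneus_R	right	67
69	Paracentral_Lobule_L	left	70
70	Paracentral_Lobule_R	right	69
71	Caudate_L	left	72
72	Caudate_R	right	71
73	Putamen_L	left	74
74	Putamen_R	right	73
75	Pallidum_L	left	76
76	Pallidum_R	right	75
77	Thalamus_L	left	78
78	Thalamus_R	right	77
79	Heschl_L	left	80
80	Heschl_R	right	79
81	Temporal_Sup_L	left	82
82	Temporal_Sup_R	right	81
83	Temporal_Pole_Sup_L	left	84
84	Temporal_Pole_Sup_R	right	83
85	Temporal_Mid_L	left	86
86	Temporal_Mid_R	right	85
87	Temporal_Pole_Mid_L	left	88
88	Temporal_Pole_Mid_R	right	87
89	Temporal_Inf_L	left	90
90	Temporal_Inf_R	right	89
91	Cerebelum_Crus1_L	left	92
92	Cerebelum_Crus1_R	right	91
93	Cerebelum_Crus2_L	left	94
94	Cerebelum_Crus2_R	right	93
95	Cerebelum_3_L	left	96
96	Cerebelum_3_R	right	95
97	Cerebelum_4_5_L	left	98
98	Cerebelum_4_5_R	right	97
99	Cerebelum_6_L	left	100
100	Cerebelum_6_R	right	99
101	Cerebelum_7b_L	left	102
102	Cerebelum_7b_R	right	101
103	Cerebelum_8_L	left	104
104	Cerebelum_8_R	right	103
105	Cerebelum_9_L	left	106
106	Cerebelum_9_R	right	105
107	Cerebelum_10_L	left	108
108	Cerebelum_10_R	right	107
109	Vermis_1_2	midline	
110	Vermis_3	midline	
111	Vermis_4_5	midline	
112	Vermis_6	midline	
113	Vermis_7	midline	
114	Vermis_8	midline	
115	Vermis_9	midline	
116	Vermis_10	midline	
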