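trial	subject	context	p_level	evidence	difficulty	choice	rt_s
1	s01	nonsocial	1	-0.5	1	-1	0.539
2	s01	social	3	0	3	1	0.794
3	s01	social	3	0	3	-1	0.539
4	s01	social	4	0.25	2	-1	0.604
5	s01	nonsocial	4	0.25	2	1	0.581
6	s01	social	4	0.25	2	-1	0.57
7	s01	nonsocial	4	0.25	2	1	0.857
8	s01	social	3	0	3	1	0.79
9	s01	nonsocial	4	0.25	2	1	0.611
10	s01	social	5	0.5	1	1	0.608
11	s01	nonsocial	5	0.5	1	1	0.583
12	s01	social	3	0	3	1	0.527
13	s01	social	5	0.5	1	1	0.55
14	s01	social	2	-0.25	2	-1	0.749
15	s01	social	3	0	3	1	0.553
16	s01	nonsocial	5	0.5	1	1	0.522
17	s01	social	2	-0.25	2	-1	0.856
18	s01	nonsocial	4	0.25	2	1	1.137
19	s01	nonsocial	1	-0.5	1	-1	0.612
20	s01	nonsocial	3	0	3	1	0.687
21	s01	nonsocial	2	-0.25	2	-1	0.718
22	s01	social	3	0	3	1	0.666
23	s01	social	1	-0.5	1	-1	0.749
24	s01	nonsocial	4	0.25	2	1	0.833
25	s01	social	2	-0.25	2	-1	1.192
26	s01	nonsocial	3	0	3	1	0.708
27	s01	nonsocial	1	-0.5	1	-1	0.518
28	s01	social	1	-0.5	1	-1	0.843
29	s01	nonsocial	2	-0.25	2	-1	0.752
30	s01	social	4	0.25	2	1	0.538
31	s01	nonsocial	3	0	3	1	0.714
32	s01	nonsocial	3	0	3	-1	1.046
33	s01	nonsocial	2	-0.25	2	-1	0.883
34	s01	nonsocial	2	-0.25	2	-1	0.529
35	s01	nonsocial	2	-0.25	2	-1	0.677
36	s01	social	4	0.25	2	1	0.637
37	s01	social	4	0.25	2	1	0.534
38	s01	nonsocial	1	-0.5	1	-1	0.509
39	s01	social	5	0.5	1	1	0.669
40	s01	nonsocial	5	0.5	1	1	0.56
41	s01	social	1	-0.5	1	-1	0.531
42	s01	nonsocial	2	-0.25	2	-1	0.613
43	s01	social	4	0.25	2	-1	0.662
44	s01	nonsocial	5	0.5	1	1	0.464
45	s01	social	4	0.25	2	1	0.622
46	s01	social	3	0	3	1	0.679
47	s01	social	3	0	3	-1	0.678
48	s01	social	3	0	3	1	0.825
49	s01	social	5	0.5	1	1	0.622
50	s01	social	2	-0.25	2	-1	0.733
51	s01	social	1	-0.5	1	-1	0.749
52	s01	social	2	-0.25	2	-1	0.665
53	s01	nonsocial	5	0.5	1	1	0.7
54	s01	nonsocial	1	-0.5	1	-1	0.555
55	s01	nonsocial	1	-0.5	1	-1	0.668
56	s01	social	5	0.5	1	1	0.605
57	s01	nonsocial	3	0	3	1	0.545
58	s01	nonsocial	4	0.25	2	1	0.699
59	s01	social	2	-0.25	2	1	0.708
60	s01	nonsocial	2	-0.25	2	-1	0.696
61	s01	nonsocial	4	0.25	2	-1	0.723
62	s01	nonsocial	2	-0.25	2	-1	0.716
63	s01	nonsocial	5	0.5	1	1	0.699
64	s01	social	5	0.5	1	1	0.562
65	s01	social	4	0.25	2	1	0.669
66	s01	social	2	-0.25	2	-1	0.491
67	s01	social	5	0.5	1	1	0.547
68	s01	social	1	-0.5	1	-1	0.572
69	s01	nonsocial	1	-0.5	1	-1	0.701
70	s01	nonsocial	2	-0.25	2	-1	0.749
71	s01	nonsocial	5	0.5	1	1	0.542
72	s01	social	3	0	3	1	0.694
73	s01	nonsocial	5	0.5	1	1	0.587
74	s01	nonsocial	4	0.25	2	1	0.738
75	s01	nonsocial	4	0.25	2	1	0.749
76	s01	social	4	0.25	2	1	0.665
77	s01	nonsocial	1	-0.5	1	-1	0.657
78	s01	nonsocial	3	0	3	1	0.629
79	s01	social	5	0.5	1	1	0.428
80	s01	nonsocial	1	-0.5	1	-1	0.794
81	s01	social	1	-0.5	1	-1	0.537
82	s01	nonsocial	5	0.5	1	1	0.528
83	s01	nonsocial	3	0	3	-1	0.687
84	s01	nonsocial	5	0.5	1	1	0.62
85	s01	nonsocial	3	0	3	-1	1.194
86	s01	social	5	0.5	1	-1	0.817
87	s01	social	2	-0.25	2	-1	0.628
88	s01	social	1	-0.5	1	-1	0.525
89	s01	social	5	0.5	1	1	0.64
90	s01	social	1	-0.5	1	-1	0.593
91	s01	nonsocial	1	-0.5	1	-1	0.684
92	s01	social	4	0.25	2	1	0.72
93	s01	social	2	-0.25	2	1	0.537
94	s01	nonsocial	3	0	3	1	0.781
95	s01	nonsocial	4	0.25	2	1	0.733
96	s01	social	1	-0.5	1	-1	0.552
97	s01	social	2	-0.25	2	-1	0.491
98	s01	nonsocial	3	0	3	-1	1.154
99	s01	social	1	-0.5	1	-1	0.649
100	s01	nonsocial	2	-0.25	2	1	1.302
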