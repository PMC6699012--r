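# Synthetic abridged US-male-style period life table (annual probability of
# death q_x at pivot ages; log-linearly interpolated to single years of age).
# Terminal age 110 is absorbing (q = 1).
age	q_annual
0	0.00640
1	0.00043
5	0.00014
10	0.00012
15	0.00044
20	0.00101
25	0.00131
30	0.00156
35	0.00185
40	0.00222
45	0.00306
50	0.00459
55	0.00712
60	0.01039
65	0.01515
70	0.02282
75	0.03541
80	0.05757
85	0.09662
90	0.16027
95	0.24526
100	0.34567
105	0.46020
110	1.00000
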