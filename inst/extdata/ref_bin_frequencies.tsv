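bin	rel_freq_exposed	rel_freq_buried
<0	10.68	3.02
0 to 10	4.31	0.82
10 to 20	4.36	1.18
20 to 30	4.87	1.38
30 to 40	5.10	1.06
40 to 50	8.88	2.07
50 to 60	6.70	7.21
60 to 70	6.24	7.56
70 to 80	6.92	7.73
80 to 90	10.73	11.82
90 to 100	31.16	56.07
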