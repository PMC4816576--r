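Subject	Accuracy (mean)	Accuracy (min)	Accuracy (max)	p (mean)	p (min)	p (max)	trials correct (mean)	trials correct (min)	trials correct (max)	trials (total)
1	68	65.6	71.6	0.006	0	0.032	170	164	179	250
2	74.416	71.429	77.273	0.015	0	0.052	114.6	110	119	154
3	79.779	72.059	83.088	0.007	0	0.030	108.5	98	113	136
4	62.069	59.914	65.086	0.081	0.043	0.125	144	139	151	232
5	66.441	59.706	69.706	0.005	0	0.014	225.9	203	237	340
6	79.015	72.727	83.333	0.006	0	0.019	104.3	96	110	132
7	70.673	63.462	75.962	0.072	0.004	0.321	73.5	66	79	104
8	68.361	63.866	71.429	0.043	0	0.208	162.7	152	170	238
9	75.783	73.478	77.826	0.012	0	0.056	174.3	169	179	230
10	61.65	54.5	66	0.120	0.039	0.372	123.3	109	132	200
11	60.63	58.661	63.386	0.078	0.002	0.327	154	149	161	254
12	57.593	56.716	58.396	0.080	0.005	0.144	308.7	304	313	536
13	58.303	56.667	61.212	0.069	0.004	0.129	192.4	187	202	330
14	61.593	57.967	65.11	0.082	0.018	0.224	224.2	211	237	364
15	67.333	56.667	73.333	0.038	0	0.126	121.2	102	132	180
16	60.533	53.333	68	0.105	0.015	0.331	90.8	80	102	150
17	56.307	54.356	59.091	0.115	0.039	0.217	297.3	287	312	528
18	77.374	74.242	81.313	0.017	0	0.056	153.2	147	161	198
19	54.543	51.923	56.01	0.144	0.043	0.259	226.9	216	233	416
20	77.436	73.077	82.051	0.013	0	0.073	120.8	114	128	156
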