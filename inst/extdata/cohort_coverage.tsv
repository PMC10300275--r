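sample	ts_mean_depth	ts_pct_ge10	wes_mean_depth	wes_pct_ge10
1	206	97	95	85
2	601	99	102	85
3	738	99	96	85
4	475	99	96	86
5	455	97	94	85
6	189	99	103	85
7	269	97	102	87
8	212	98	96	87
9	253	98	96	87
10	197	98	102	90
11	193	97	100	90
12	179	97	106	91
13	178	94	94	89
14	122	93	103	91
15	135	91	97	86
16	658	99	119	92
17	229	98	112	87
18	200	98	115	88
19	221	98	105	87
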