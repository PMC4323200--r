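1	2	1
1	3	1
1	4	1
1	5	1
1	6	1
1	7	1
1	8	1
1	9	1
1	11	1
1	12	1
1	13	1
1	14	1
1	18	1
1	20	1
1	22	1
1	32	1
2	3	1
2	4	1
2	8	1
2	14	1
2	18	1
2	20	1
2	22	1
2	31	1
3	4	1
3	8	1
3	9	1
3	10	1
3	14	1
3	28	1
3	29	1
3	33	1
4	8	1
4	13	1
4	14	1
5	7	1
5	11	1
6	7	1
6	11	1
6	17	1
7	17	1
9	31	1
9	33	1
9	34	1
10	34	1
14	34	1
15	33	1
15	34	1
16	33	1
16	34	1
19	33	1
19	34	1
20	34	1
21	33	1
21	34	1
23	33	1
23	34	1
24	26	1
24	28	1
24	30	1
24	33	1
24	34	1
25	26	1
25	28	1
25	32	1
26	32	1
27	30	1
27	34	1
28	34	1
29	32	1
29	34	1
30	33	1
30	34	1
31	33	1
31	34	1
32	33	1
32	34	1
33	34	1
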