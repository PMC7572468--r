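hex	hexnac	neuac	fuc
3	2	0	0
3	2	0	1
4	2	0	0
3	3	0	0
3	2	1	0
3	2	0	2
4	2	0	1
5	2	0	0
3	3	0	1
4	3	0	0
3	4	0	0
3	2	1	1
3	2	0	3
4	2	1	0
4	2	0	2
5	2	0	1
6	2	0	0
3	3	1	0
3	3	0	2
4	3	0	1
5	3	0	0
3	4	0	1
4	4	0	0
3	2	2	0
3	2	1	2
4	2	1	1
4	2	0	3
3	5	0	0
5	2	1	0
5	2	0	2
6	2	0	1
3	3	1	1
3	3	0	3
7	2	0	0
4	3	1	0
4	3	0	2
5	3	0	1
6	3	0	0
3	4	1	0
3	4	0	2
4	4	0	1
3	2	2	1
3	2	1	3
5	4	0	0
4	2	2	0
4	2	1	2
3	5	0	1
5	2	1	1
5	2	0	3
4	5	0	0
6	2	1	0
6	2	0	2
3	3	2	0
3	3	1	2
7	2	0	1
4	3	1	1
4	3	0	3
8	2	0	0
3	6	0	0
5	3	1	0
5	3	0	2
6	3	0	1
3	4	1	1
3	4	0	3
7	3	0	0
4	4	1	0
4	4	0	2
3	2	3	0
3	2	2	2
5	4	0	1
4	2	2	1
4	2	1	3
6	4	0	0
3	5	1	0
3	5	0	2
5	2	2	0
5	2	1	2
4	5	0	1
6	2	1	1
6	2	0	3
3	3	2	1
3	3	1	3
5	5	0	0
7	2	1	0
7	2	0	2
4	3	2	0
4	3	1	2
8	2	0	1
3	6	0	1
5	3	1	1
5	3	0	3
9	2	0	0
4	6	0	0
6	3	1	0
6	3	0	2
3	4	2	0
3	4	1	2
7	3	0	1
4	4	1	1
4	4	0	3
8	3	0	0
3	7	0	0
3	2	3	1
3	2	2	3
5	4	1	0
5	4	0	2
4	2	3	0
4	2	2	2
6	4	0	1
3	5	1	1
3	5	0	3
5	2	2	1
5	2	1	3
7	4	0	0
4	5	1	0
4	5	0	2
6	2	2	0
6	2	1	2
3	3	3	0
3	3	2	2
5	5	0	1
7	2	1	1
7	2	0	3
4	3	2	1
4	3	1	3
6	5	0	0
8	2	1	0
8	2	0	2
3	6	1	0
3	6	0	2
5	3	2	0
5	3	1	2
9	2	0	1
4	6	0	1
6	3	1	1
6	3	0	3
10	2	0	0
3	4	2	1
3	4	1	3
5	6	0	0
7	3	1	0
7	3	0	2
4	4	2	0
4	4	1	2
8	3	0	1
3	7	0	1
3	2	4	0
3	2	3	2
5	4	1	1
5	4	0	3
9	3	0	0
4	7	0	0
4	2	3	1
4	2	2	3
6	4	1	0
6	4	0	2
3	5	2	0
3	5	1	2
5	2	3	0
5	2	2	2
7	4	0	1
4	5	1	1
4	5	0	3
6	2	2	1
6	2	1	3
8	4	0	0
3	3	3	1
3	3	2	3
5	5	1	0
5	5	0	2
7	2	2	0
7	2	1	2
4	3	3	0
4	3	2	2
6	5	0	1
8	2	1	1
8	2	0	3
3	6	1	1
3	6	0	3
5	3	2	1
5	3	1	3
7	5	0	0
9	2	1	0
9	2	0	2
4	6	1	0
4	6	0	2
6	3	2	0
6	3	1	2
3	4	3	0
10	2	0	1
3	4	2	2
5	6	0	1
7	3	1	1
7	3	0	3
11	2	0	0
4	4	2	1
4	4	1	3
6	6	0	0
8	3	1	0
8	3	0	2
3	7	1	0
3	7	0	2
3	2	4	1
3	2	3	3
5	4	2	0
5	4	1	2
9	3	0	1
4	7	0	1
4	2	4	0
4	2	3	2
6	4	1	1
6	4	0	3
10	3	0	0
3	5	2	1
3	5	1	3
5	7	0	0
5	2	3	1
5	2	2	3
7	4	1	0
7	4	0	2
4	5	2	0
4	5	1	2
6	2	3	0
6	2	2	2
8	4	0	1
3	3	4	0
3	3	3	2
5	5	1	1
5	5	0	3
7	2	2	1
7	2	1	3
9	4	0	0
4	3	3	1
4	3	2	3
6	5	1	0
6	5	0	2
8	2	2	0
8	2	1	2
3	6	2	0
3	6	1	2
5	3	3	0
5	3	2	2
7	5	0	1
9	2	1	1
9	2	0	3
4	6	1	1
4	6	0	3
6	3	2	1
6	3	1	3
8	5	0	0
10	2	1	0
3	4	3	1
10	2	0	2
3	4	2	3
5	6	1	0
5	6	0	2
7	3	2	0
7	3	1	2
4	4	3	0
11	2	0	1
4	4	2	2
6	6	0	1
8	3	1	1
8	3	0	3
3	7	1	1
3	7	0	3
3	2	4	2
12	2	0	0
5	4	2	1
5	4	1	3
7	6	0	0
9	3	1	0
9	3	0	2
4	7	1	0
4	7	0	2
4	2	4	1
4	2	3	3
6	4	2	0
6	4	1	2
3	5	3	0
10	3	0	1
3	5	2	2
5	7	0	1
5	2	4	0
5	2	3	2
7	4	1	1
7	4	0	3
11	3	0	0
4	5	2	1
4	5	1	3
6	7	0	0
6	2	3	1
6	2	2	3
8	4	1	0
8	4	0	2
3	3	4	1
3	3	3	3
5	5	2	0
5	5	1	2
7	2	3	0
7	2	2	2
9	4	0	1
4	3	4	0
4	3	3	2
6	5	1	1
6	5	0	3
8	2	2	1
8	2	1	3
10	4	0	0
3	6	2	1
3	6	1	3
5	3	3	1
5	3	2	3
7	5	1	0
7	5	0	2
9	2	2	0
9	2	1	2
4	6	2	0
4	6	1	2
6	3	3	0
6	3	2	2
8	5	0	1
3	4	4	0
10	2	1	1
3	4	3	2
10	2	0	3
5	6	1	1
5	6	0	3
7	3	2	1
7	3	1	3
9	5	0	0
11	2	1	0
4	4	3	1
11	2	0	2
4	4	2	3
6	6	1	0
6	6	0	2
8	3	2	0
8	3	1	2
3	7	2	0
3	7	1	2
3	2	4	3
5	4	3	0
12	2	0	1
5	4	2	2
7	6	0	1
9	3	1	1
9	3	0	3
4	7	1	1
4	7	0	3
4	2	4	2
6	4	2	1
6	4	1	3
8	6	0	0
10	3	1	0
3	5	3	1
10	3	0	2
3	5	2	3
5	7	1	0
5	7	0	2
5	2	4	1
5	2	3	3
7	4	2	0
7	4	1	2
4	5	3	0
11	3	0	1
4	5	2	2
6	7	0	1
6	2	4	0
6	2	3	2
8	4	1	1
8	4	0	3
3	3	4	2
12	3	0	0
5	5	2	1
5	5	1	3
7	7	0	0
7	2	3	1
7	2	2	3
9	4	1	0
9	4	0	2
4	3	4	1
4	3	3	3
6	5	2	0
6	5	1	2
8	2	3	0
8	2	2	2
3	6	3	0
10	4	0	1
3	6	2	2
5	3	4	0
5	3	3	2
7	5	1	1
7	5	0	3
9	2	2	1
9	2	1	3
11	4	0	0
4	6	2	1
4	6	1	3
6	3	3	1
6	3	2	3
8	5	1	0
8	5	0	2
10	2	2	0
3	4	4	1
10	2	1	2
3	4	3	3
5	6	2	0
5	6	1	2
7	3	3	0
7	3	2	2
9	5	0	1
4	4	4	0
11	2	1	1
4	4	3	2
11	2	0	3
6	6	1	1
6	6	0	3
8	3	2	1
8	3	1	3
10	5	0	0
3	7	2	1
3	7	1	3
12	2	1	0
5	4	3	1
12	2	0	2
5	4	2	3
7	6	1	0
7	6	0	2
9	3	2	0
9	3	1	2
4	7	2	0
4	7	1	2
4	2	4	3
6	4	3	0
6	4	2	2
8	6	0	1
3	5	4	0
10	3	1	1
3	5	3	2
10	3	0	3
5	7	1	1
5	7	0	3
5	2	4	2
7	4	2	1
7	4	1	3
9	6	0	0
11	3	1	0
4	5	3	1
11	3	0	2
4	5	2	3
6	7	1	0
6	7	0	2
6	2	4	1
6	2	3	3
8	4	2	0
8	4	1	2
3	3	4	3
5	5	3	0
12	3	0	1
5	5	2	2
7	7	0	1
7	2	4	0
7	2	3	2
9	4	1	1
9	4	0	3
4	3	4	2
6	5	2	1
6	5	1	3
8	7	0	0
8	2	3	1
8	2	2	3
10	4	1	0
3	6	3	1
10	4	0	2
3	6	2	3
5	3	4	1
5	3	3	3
7	5	2	0
7	5	1	2
9	2	3	0
9	2	2	2
4	6	3	0
11	4	0	1
4	6	2	2
6	3	4	0
6	3	3	2
8	5	1	1
8	5	0	3
10	2	2	1
3	4	4	2
10	2	1	3
12	4	0	0
5	6	2	1
5	6	1	3
7	3	3	1
7	3	2	3
9	5	1	0
9	5	0	2
11	2	2	0
4	4	4	1
11	2	1	2
4	4	3	3
6	6	2	0
6	6	1	2
8	3	3	0
8	3	2	2
3	7	3	0
10	5	0	1
3	7	2	2
5	4	4	0
12	2	1	1
5	4	3	2
12	2	0	3
7	6	1	1
7	6	0	3
9	3	2	1
9	3	1	3
11	5	0	0
4	7	2	1
4	7	1	3
6	4	3	1
6	4	2	3
8	6	1	0
8	6	0	2
10	3	2	0
3	5	4	1
10	3	1	2
3	5	3	3
5	7	2	0
5	7	1	2
5	2	4	3
7	4	3	0
7	4	2	2
9	6	0	1
4	5	4	0
11	3	1	1
4	5	3	2
11	3	0	3
6	7	1	1
6	7	0	3
6	2	4	2
8	4	2	1
8	4	1	3
10	6	0	0
12	3	1	0
5	5	3	1
12	3	0	2
5	5	2	3
7	7	1	0
7	7	0	2
7	2	4	1
7	2	3	3
9	4	2	0
9	4	1	2
4	3	4	3
6	5	3	0
6	5	2	2
8	7	0	1
8	2	4	0
8	2	3	2
3	6	4	0
10	4	1	1
3	6	3	2
10	4	0	3
5	3	4	2
7	5	2	1
7	5	1	3
9	7	0	0
9	2	3	1
9	2	2	3
11	4	1	0
4	6	3	1
11	4	0	2
4	6	2	3
6	3	4	1
6	3	3	3
8	5	2	0
8	5	1	2
10	2	3	0
10	2	2	2
3	4	4	3
5	6	3	0
12	4	0	1
5	6	2	2
7	3	4	0
7	3	3	2
9	5	1	1
9	5	0	3
11	2	2	1
4	4	4	2
11	2	1	3
6	6	2	1
6	6	1	3
8	3	3	1
8	3	2	3
10	5	1	0
3	7	3	1
10	5	0	2
3	7	2	3
12	2	2	0
5	4	4	1
12	2	1	2
5	4	3	3
7	6	2	0
7	6	1	2
9	3	3	0
9	3	2	2
4	7	3	0
11	5	0	1
4	7	2	2
6	4	4	0
6	4	3	2
8	6	1	1
8	6	0	3
10	3	2	1
3	5	4	2
10	3	1	3
12	5	0	0
5	7	2	1
5	7	1	3
7	4	3	1
7	4	2	3
9	6	1	0
9	6	0	2
11	3	2	0
4	5	4	1
11	3	1	2
4	5	3	3
6	7	2	0
6	7	1	2
6	2	4	3
8	4	3	0
8	4	2	2
10	6	0	1
5	5	4	0
12	3	1	1
5	5	3	2
12	3	0	3
7	7	1	1
7	7	0	3
7	2	4	2
9	4	2	1
9	4	1	3
11	6	0	0
6	5	3	1
6	5	2	3
8	7	1	0
8	7	0	2
8	2	4	1
8	2	3	3
10	4	2	0
3	6	4	1
10	4	1	2
3	6	3	3
5	3	4	3
7	5	3	0
7	5	2	2
9	7	0	1
9	2	4	0
9	2	3	2
4	6	4	0
11	4	1	1
4	6	3	2
11	4	0	3
6	3	4	2
8	5	2	1
8	5	1	3
10	7	0	0
10	2	3	1
10	2	2	3
12	4	1	0
5	6	3	1
12	4	0	2
5	6	2	3
7	3	4	1
7	3	3	3
9	5	2	0
9	5	1	2
11	2	3	0
11	2	2	2
4	4	4	3
6	6	3	0
6	6	2	2
8	3	4	0
8	3	3	2
3	7	4	0
10	5	1	1
3	7	3	2
10	5	0	3
12	2	2	1
5	4	4	2
12	2	1	3
7	6	2	1
7	6	1	3
9	3	3	1
9	3	2	3
11	5	1	0
4	7	3	1
11	5	0	2
4	7	2	3
6	4	4	1
6	4	3	3
8	6	2	0
8	6	1	2
10	3	3	0
10	3	2	2
3	5	4	3
5	7	3	0
12	5	0	1
5	7	2	2
7	4	4	0
7	4	3	2
9	6	1	1
9	6	0	3
11	3	2	1
4	5	4	2
11	3	1	3
6	7	2	1
6	7	1	3
8	4	3	1
8	4	2	3
10	6	1	0
10	6	0	2
12	3	2	0
5	5	4	1
12	3	1	2
5	5	3	3
7	7	2	0
7	7	1	2
7	2	4	3
9	4	3	0
9	4	2	2
11	6	0	1
6	5	4	0
6	5	3	2
8	7	1	1
8	7	0	3
8	2	4	2
10	4	2	1
3	6	4	2
10	4	1	3
12	6	0	0
7	5	3	1
7	5	2	3
9	7	1	0
9	7	0	2
9	2	4	1
9	2	3	3
11	4	2	0
4	6	4	1
11	4	1	2
4	6	3	3
6	3	4	3
8	5	3	0
8	5	2	2
10	7	0	1
10	2	4	0
10	2	3	2
5	6	4	0
12	4	1	1
5	6	3	2
7	3	4	2
9	5	2	1
9	5	1	3
11	7	0	0
11	2	3	1
11	2	2	3
6	6	3	1
6	6	2	3
8	3	4	1
8	3	3	3
10	5	2	0
3	7	4	1
10	5	1	2
3	7	3	3
12	2	3	0
12	2	2	2
5	4	4	3
7	6	3	0
7	6	2	2
9	3	4	0
9	3	3	2
4	7	4	0
11	5	1	1
4	7	3	2
6	4	4	2
8	6	2	1
8	6	1	3
10	3	3	1
10	3	2	3
12	5	1	0
5	7	3	1
5	7	2	3
7	4	4	1
7	4	3	3
9	6	2	0
9	6	1	2
11	3	3	0
11	3	2	2
4	5	4	3
6	7	3	0
6	7	2	2
8	4	4	0
8	4	3	2
10	6	1	1
12	3	2	1
5	5	4	2
7	7	2	1
7	7	1	3
9	4	3	1
9	4	2	3
11	6	1	0
6	5	4	1
6	5	3	3
8	7	2	0
8	7	1	2
8	2	4	3
10	4	3	0
10	4	2	2
3	6	4	3
7	5	4	0
7	5	3	2
9	7	1	1
9	2	4	2
11	4	2	1
4	6	4	2
8	5	3	1
8	5	2	3
10	7	1	0
10	2	4	1
10	2	3	3
12	4	2	0
5	6	4	1
5	6	3	3
7	3	4	3
9	5	3	0
9	5	2	2
11	2	4	0
11	2	3	2
6	6	4	0
6	6	3	2
8	3	4	2
10	5	2	1
3	7	4	2
12	2	3	1
7	6	3	1
7	6	2	3
9	3	4	1
9	3	3	3
11	5	2	0
4	7	4	1
4	7	3	3
6	4	4	3
8	6	3	0
8	6	2	2
10	3	4	0
10	3	3	2
5	7	4	0
5	7	3	2
7	4	4	2
9	6	2	1
11	3	3	1
6	7	3	1
6	7	2	3
8	4	4	1
8	4	3	3
10	6	2	0
12	3	3	0
5	5	4	3
7	7	3	0
7	7	2	2
9	4	4	0
9	4	3	2
6	5	4	2
8	7	2	1
10	4	3	1
7	5	4	1
7	5	3	3
9	7	2	0
9	2	4	3
11	4	3	0
4	6	4	3
8	5	4	0
8	5	3	2
10	2	4	2
5	6	4	2
9	5	3	1
11	2	4	1
6	6	4	1
6	6	3	3
8	3	4	3
10	5	3	0
3	7	4	3
12	2	4	0
7	6	4	0
7	6	3	2
9	3	4	2
4	7	4	2
8	6	3	1
10	3	4	1
5	7	4	1
5	7	3	3
7	4	4	3
9	6	3	0
11	3	4	0
6	7	4	0
6	7	3	2
8	4	4	2
7	7	3	1
9	4	4	1
6	5	4	3
8	7	3	0
10	4	4	0
7	5	4	2
8	5	4	1
5	6	4	3
9	5	4	0
6	6	4	2
7	6	4	1
4	7	4	3
8	6	4	0
5	7	4	2
6	7	4	1
7	7	4	0
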