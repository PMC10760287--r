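rs0856018	rs1343338	rs4835079	rs4732495	rs6841049	rs7168485	rs6920574	rs5779372	rs5446563	rs4548938
2	1	2	1	2	1	1	1	0	0
1	1	1	0	1	0	0	1	1	2
0	0	0	0	0	0	0	0	0	1
1	1	1	1	1	1	0	0	0	2
1	1	0	0	2	1	1	0	1	0
0	0	0	0	1	1	1	1	0	2
1	2	1	0	1	1	0	1	0	1
1	1	2	1	1	1	0	0	0	0
2	0	2	1	1	0	0	1	1	1
1	1	1	0	1	2	0	1	0	1
1	1	1	1	2	1	0	1	0	0
2	2	2	2	2	0	0	0	0	0
1	0	2	1	0	2	0	2	0	0
1	1	2	1	2	1	1	2	0	2
0	1	1	0	0	0	0	1	0	0
2	2	2	2	2	1	0	0	1	1
0	0	0	0	1	1	0	2	1	0
1	1	1	1	0	0	0	0	1	0
0	0	0	0	0	1	0	0	1	0
1	1	1	1	1	1	0	2	0	1
1	0	1	0	0	0	0	0	0	0
1	0	0	1	0	1	0	1	0	0
1	0	1	0	1	1	0	2	1	1
0	0	0	0	1	0	0	0	0	0
1	0	1	0	2	2	1	1	0	0
0	0	0	0	0	1	0	1	2	1
0	0	0	0	1	1	0	2	2	1
0	0	2	1	1	0	0	1	0	1
1	1	2	1	1	0	0	1	0	2
1	0	0	1	1	2	1	1	1	1
0	0	0	0	1	1	1	1	0	0
0	0	0	0	2	1	0	1	1	0
2	2	2	2	1	2	0	1	0	1
0	0	1	0	2	0	1	1	1	0
1	0	1	1	2	0	0	0	1	0
1	1	2	1	2	1	0	1	0	0
1	1	1	1	1	0	0	2	0	0
1	1	2	1	2	0	0	1	1	1
2	1	2	1	0	0	0	1	0	2
0	1	1	0	1	2	0	1	0	0
2	1	2	1	1	1	0	2	0	0
1	0	1	0	0	2	0	1	0	1
1	1	1	1	0	1	0	0	1	0
0	0	0	0	0	0	0	2	1	0
1	1	1	0	1	0	0	1	1	0
0	0	0	0	0	0	0	1	1	0
0	0	0	0	2	2	0	1	2	1
1	1	1	1	0	1	0	1	2	1
0	0	0	0	1	2	0	1	0	1
0	0	0	0	1	1	0	1	0	0
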