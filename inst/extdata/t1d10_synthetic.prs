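#T1D10-like
A	rs0856018	C	1.1215883318334816
A	rs1343338	C	0.56424303548410526
A	rs4835079	G	0.71315915363375093
A	rs4732495	T	0.59915520676877343
A	rs6841049	T	0.081805571215227246
A	rs7168485	T	0.094759772077668461
A	rs6920574	C	0.19232226823223758
A	rs5779372	T	0.28338541843695569
A	rs5446563	A	0.34790228438796478
A	rs4548938	G	0.23307358423480767
I	rs0856018	rs1343338	state_indicator	1	1	2.1508704670704901
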