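position	Hs_bIII	Mm_bIII	Gg_bIII	Gj_bIII	Xl_bIII	Ss_bIII	Hs_bI	Hs_bIIA	Hs_bIIB	Hs_bIVA	Hs_bIVB	Hs_bV	Hs_bVI
33	S	S	S	S	C	T	T	T	T	L	T	A	A
35	N	N	N	N	N	N	T	S	T	T	T	G	S
37	V	V	V	V	I	E	H	H	H	H	H	V	R
48	S	S	S	S	S	S	S	V	N	N	N	N	S
55	S	S	S	S	S	S	T	A	T	T	T	S	Y
56	S	S	S	S	S	S	G	G	G	G	G	S	G
57	H	H	H	H	L	S	G	N	N	G	G	Q	R
80	A	A	A	A	A	T	P	P	P	P	P	P	K
83	H	H	H	H	H	Q	Q	Q	Q	Q	Q	Q	A
84	L	L	L	L	L	L	I	I	I	I	I	I	L
91	I	I	I	I	I	I	V	V	V	V	V	I	V
124	C	C	C	C	C	C	A	S	S	A	A	C	S
126	N	N	N	N	N	N	S	S	S	S	S	H	S
155	V	V	V	V	V	I	I	I	I	I	I	I	I
189	I	I	I	I	I	I	V	V	V	V	V	V	I
218	A	A	A	A	A	P	T	T	T	T	T	T	T
239	S	S	S	S	S	S	C	C	C	C	C	S	S
275	A	A	A	A	A	A	S	S	S	S	S	S	A
315	T	T	T	A	T	M	A	A	A	A	A	T	C
332	A	A	A	A	A	A	N	N	N	S	V	A	S
333	I	I	I	I	I	I	V	V	V	V	Q	I	V
335	S	S	S	S	S	S	N	N	N	S	K	S	T
351	V	V	V	V	V	V	T	T	T	T	T	V	V
364	S	S	S	S	S	S	A	S	S	A	P	A	A
365	S	S	S	S	S	A	V	A	A	A	A	S	A
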