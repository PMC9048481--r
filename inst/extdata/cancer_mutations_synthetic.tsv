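sample_id	isotype	position	ref	obs	grade	chemo
P1	betaIVB	124	A	C	high	unknown
P1	betaIVB	126	S	N	high	unknown
P1	betaIVB	155	I	V	high	unknown
P1	betaIVB	189	V	I	high	unknown
P1	betaIVB	218	T	A	high	unknown
P1	betaIVB	239	C	S	high	unknown
P2	betaIVB	275	S	A	high	unknown
P2	betaIVB	315	A	T	high	unknown
P2	betaIVB	332	V	A	high	unknown
P2	betaIVB	333	Q	I	high	unknown
P2	betaIVB	335	K	S	high	unknown
P2	betaIVB	351	T	V	high	unknown
P2	betaIVB	365	A	S	high	unknown
P3	betaIVB	332	V	A	high	unknown
P3	betaIVB	333	Q	I	high	unknown
P3	betaIVB	335	K	S	high	unknown
P3	betaIVB	351	T	V	high	unknown
P3	betaIVB	365	A	S	high	unknown
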