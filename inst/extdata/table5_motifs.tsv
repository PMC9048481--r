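table	column	cluster	hexamer	region239	printed_hmbg	printed_hmbg_and_v	printed_vert
table3	betaIII	Yes	CENCDC	TTSL	25	12	8
table3	So1	No	AESCDC	TTCL	5	3	1
table3	So2	Yes	CENCDC	TTCL	4	1	3
table3	Ed	Yes	CEGCEC	TTCL	7	4	3
table3	Ob	Yes	CEGCEC	TTCL	7	4	3
table3	Do	No	AESCDC	TTCL	1	0	0
table3	Ac	No	SENCDC	TTCL	2	0	0
table3	Cg	No	AESCDC	TTCL	1	0	0
table3	Ls1	No	AENCDC	TTCL	3	1	0
table3	Ls2	No	SENCDC	TTSL	7	2	2
table3	Hd	No	AESCDC	TTCL	2	1	0
table3	Dm1	No	AESCDC	TTCL	4	2	1
table3	Dm2	Yes	CENCDC	TTCL	7	4	2
table3	Em	Yes	CEACDC	TTSL	4	3	3
table3	Nc	No	AEGCDC	TVSL	6	3	2
table3	At	No	AENSDC	TCCL	7	3	2
table3	Gi	No	SEACDC	TSCL	3	2	1
table3	Tp	No	AEGCDC	TCCL	2	0	1
table1	Hs_bI	No	AESCDC	TTCL	1	0	0
table1	Hs_bIIA	No	SESCDC	TTCL	1	1	0
table1	Hs_bIIB	No	SESCDC	TTCL	1	0	0
table1	Hs_bIII	Yes	CENCDC	TTSL	25	12	8
table1	Hs_bIVA	No	AESCDC	TTCL	1	1	0
table1	Hs_bIVB	No	AESCDC	TTCL	0	0	0
table1	Hs_bV	Yes	CEHCDC	TTSL	12	12	4
table1	Hs_bVI	No	SESCDC	TTSL	6	2	5
table2	Gg_bVI	Yes	CESCDC	TTSL	9	4	7
table2	Hs_bVI	No	SESCDC	TTSL	6	2	5
table2	cod_bVI	Yes	CENCDC	NA	NA	NA	NA
table2	Hs_bIII	Yes	CENCDC	TTSL	25	12	8
table2	Hs_bV	Yes	CEHCDC	TTSL	12	12	4
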