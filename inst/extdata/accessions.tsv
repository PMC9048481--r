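label	species	accession
Hs_bIII	Homo sapiens	AAL28094
Mm_bIII	Mus musculus	NP_075768
Gg_bIII	Gallus gallus	NP_001383082
Gj_bIII	Gekko japonicus	AFD53918
Xl_bIII	Xenopus laevis	NP_001088455
Ss_bIII	Salmo salar	XP_013982514
Hs_bI	Homo sapiens	BAE78618
Hs_bIIA	Homo sapiens	NP_001060
Hs_bIIB	Homo sapiens	NP_821080
Hs_bIVA	Homo sapiens	NP_001276058
Hs_bIVB	Homo sapiens	AAN87335
Hs_bV	Homo sapiens	Q9BUF5
Hs_bVI	Homo sapiens	NP_110400
Mm_bVI	Mus musculus	NP_001074440
Gg_bVI	Gallus gallus	NP_990776
duck_bVI	Anas platyrhynchos	XP_005010451
gecko_bVI	Gekko japonicus	XP_015268461
turtle_bVI	Chelonia mydas	XP_007059846
Xl_bVI	Xenopus laevis	XP_031750537
Channa_bVI	Channa argus	KAF3690084
molly_bVI	Poecilia formosa	XP_007548412
cod_bVI	Gadus morhua	XP_030204426
So1	Sepia officinalis	CCG28034
So2	Sepia officinalis	CCG28035
Ed	Enteroctopus dofleini	AAA16611
Ob	Octopus bimaculoides	KOF91916
Do	Doryteuthis pealeii	AAU11524
Ac	Aplysia californica	NP_001191530
Cg	Crassostrea gigas	BAD80737
Ls1	Lymnaea stagnalis	AOV18890
Ls2	Lymnaea stagnalis	AOV18892
Hd	Haliotis diversicolor	AEW42984
Dm1	Drosophila melanogaster	NP_523795
Dm2	Drosophila melanogaster	NP_001286835
Em	Echinococcus multilocularis	CDI98193
Nc	Neurospora crassa	AAA33617
At	Arabidopsis thaliana	AAA32757
Gi	Giardia lamblia	XP_001707388
Tp	Tetrahymena pyriformis	CAA31258
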