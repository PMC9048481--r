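group	label	tail
vertebrate_betaIII	Homo	YQDATAEEEGEMYEDDEEESEAQGPK
vertebrate_betaIII	Mus	YQDATAEEEGEMYEDDDEESEAQGPK
vertebrate_betaIII	Gallus	YQDATAEEEGEMYEDDEEESEAQGAK
vertebrate_betaIII	Gekko	YQDATAEEEGEMYEDDEEESEAQGAK
vertebrate_betaIII	Xenopus	YQDATAEEEGEMYEDDEEESEAQGK
vertebrate_betaIII	Salmo	YQDATTEEEGEMYEDDEEESESQAR
other_human	betaI	YQDATAEEEEDFGEEAEEEA
other_human	betaIIA	YQDATADEQGEFEEEEGEDEA
other_human	betaIIB	YQDATADEQGEFEEEEGEDEA
other_human	betaIVA	YQDATAEEGEFEEEAEEEVA
other_human	betaIVB	YQDATAEEEGEFEEGAEEEVA
other_human	betaV	YQDATANDGEEAFEDEEEEIDG
other_human	betaVI	FQDAKAVLEEDEEVTEEAEMEPEDKGH
cephalopod	Sepia_iso1	YQDATAEEEAEMDEEEEDVA
cephalopod	Sepia_iso2	YQDATTEEEILIEEAEDEEA
cephalopod	Enteroctopus	YQEARSTDSDEYDNEEYYNQQEE
cephalopod	Octopus	YQEARATDSDEYDDEDQYNEQE
cephalopod	Doryteuthis	YQDATAEEEGEFEEEGEEDA
other_mollusk	Aplysia	YQDATAEDEGEFDEEEGDEGGEEYA
other_mollusk	Crassostrea	YQDATAEEEGEFEEEEGEEEAQ
other_mollusk	Lymnaea_iso1	YQDATAEDEGEFDEEEAEGEGQEYA
other_mollusk	Lymnaea_iso2	YQEATIDEDVEVEEGADEDAGDL
other_mollusk	Haliotis	YQDATAEEEGEFDEEEGEADEA
other_invertebrate	Drosophila_56D	YQEATADEDAEFEEEQEAEVDEN
other_invertebrate	Drosophila_60D	LVSEYQQYQEATADDEFDPEVNQEEVEGDCI
other_invertebrate	Nasonia	YQEATTEEDFETEDAGDDFETCDQE
other_invertebrate	Bombyx	YQEATAEDDTEFDQEDLEELAQDEHHD
other_invertebrate	Echinococcus	EYQQYQEVGIDDDYGEEEAAPEE
other_eukaryote	Neurospora	YQDAGVDEEEEEYEEEAPLEGEE
other_eukaryote	Arabidopsis	YQDATAGEEEYEEEEEEYET
other_eukaryote	Giardia	YQEAGVDEGEEFEEEEDFGDEYA
other_eukaryote	Tetrahymena	YQDATAEEEGEFEEEEGEN
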