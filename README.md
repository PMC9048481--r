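# tubsig — beta-tubulin isotype signature analysis

Vertebrate beta-tubulins come in several isotypes (betaI, betaIIA/B, betaIII,
betaIVA/B, betaV, betaVI) that are nearly identical over the ~430-residue
core but diverge at a small, evolutionarily stable set of positions. The
betaIII isotype — normally restricted to neurons and testis, and
over-expressed in aggressive tumours — is defined by:

* characteristic residues at **25 canonical positions**
  (33, 35, 37, 48, 55, 56, 57, 80, 83, 84, 91, 124, 126, 155, 189, 218, 239,
  275, 315, 332, 333, 335, 351, 364, 365, numbered on human betaIII);
* a **cysteine cluster** with CXXCXC topography at positions 124–129
  (CENCDC in betaIII), present when cysteines occupy 124, 127 and 129;
* **serine at 239** where most isotypes carry an oxidation-prone cysteine
  (context tetramer TTSL vs TTCL at 237–240);
* a distinctive **C-terminal tail** (canonical 425 onward) ending in a basic
  residue, with landmark residues M436, Y437 and S444.

For an arbitrary beta-tubulin sequence `q` and a position set `P`, tubsig
computes the match count

    m(q, P) = | { p in P : q[p] == betaIII[p] } |

after placing `q` on betaIII coordinates by pairwise global alignment
(Needleman–Wunsch, BLOSUM62, gap open 10, gap extend 0.5, via Biostrings).
Besides the full 25-position set, two curated subsets are built in:
`universal8`, the eight positions conserved across vertebrate betaIII and
distinct from betaI/betaII/betaIV; and `betaV12`, the twelve positions at
which human betaV carries the betaIII residue. A third set,
`cancer_mutated17`, lists the signature positions observed mutated in
breast-tumour beta-tubulins and drives the classifier that labels tumour
substitutions as convergent toward betaIII.

The package bundles the published residue matrices, C-terminal tails and
motif calls as plain-text fixtures, plus a seeded generator of tubulin-like
synthetic sequences with ground-truth manifests for end-to-end testing. The
bundled alignment reference is a clearly labelled synthetic stand-in whose
documented positions are exact (see the methods vignette,
`vignettes/signature-analysis.Rmd`).

## Worked example

Score the bundled invertebrate residue matrix against betaIII:

```r
library(tubsig)

rep3 <- compare_report(fixture = "table3")
rep3[rep3$id %in% c("So1", "So2", "Ob", "Dm1"), ]
#>   id match_all25 match_betaV12 match_universal8 cluster hexamer region239
#>  So1           5             3                1      No  AESCDC      TTCL
#>  So2           4             1                1     Yes  CENCDC      TTCL
#>   Ob           7             4                3     Yes  CEGCEC      TTCL
#>  Dm1           4             2                1      No  AESCDC      TTCL
```

(So1/So2 are the two *Sepia officinalis* isotypes; Ob is *Octopus
bimaculoides*; Dm1 is *Drosophila* betaTub56D.)

Number a full-length sequence and profile its tail:

```r
ref <- reference_record()
map <- build_numbering_map(ref$residues)
map
#> NumberingMap: 450/450 query residues mapped onto canonical 1-450
#>   identity 100.0%; 0 insertion block(s); 0 unmapped canonical position(s)

tail <- split_tail(ref$residues, map)$tail
cterminal_features(tail, map = map, record = ref$residues)
#> $tail:             "YQDATAEEEGEMYEDDEEESEAQGPK"
#> $length:           26
#> $terminal_residue: "K"   $terminal_basic: TRUE
#> $acidic_count:     12
#> $has_M436 / $has_Y437 / $has_S444: TRUE TRUE TRUE
```

A command-line front end with `compare`, `ctermini`, `mutations`,
`simulate` and `fixtures` subcommands is installed at
`system.file("scripts", "tubsig.R", package = "tubsig")`.

## Package layout

| Path | Contents |
| --- | --- |
| `R/numbering.R` | FASTA I/O, canonical numbering maps, tail splitting |
| `R/signature.R` | signature scheme, fixture loading, match counting |
| `R/motifs.R` | cysteine-cluster and region-239 calls, tail features |
| `R/mutations.R` | tumour substitution classification and summaries |
| `R/synthetic.R` | seeded synthetic-sequence generator with manifests |
| `R/reports.R` | table-level reports and CLI backends |
| `inst/extdata/` | transcribed residue/tail/motif fixtures (plain TSV/FASTA) |
| `inst/scripts/tubsig.R` | command-line front end |
| `vignettes/signature-analysis.Rmd` | methods, parameter rationale, limitations |

## Limitations

Numbering is strictly pairwise against one reference and refuses queries
below 40% alignment identity; convergence counts are raw tallies with no
significance machinery; the synthetic generator uses i.i.d. substitution
noise, not a phylogenetic model. See the methods vignette for the full
discussion.
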