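---
title: "The beta-III tubulin residue signature: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The beta-III tubulin residue signature: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubsig)
```

## The problem

Vertebrate beta-tubulin exists as several isotypes (betaI, betaIIA/B,
betaIII, betaIVA/B, betaV, betaVI) that are nearly identical in sequence but
differ at a small, evolutionarily stable set of positions. The betaIII
isotype — restricted largely to neurons, testis and advanced tumours — is
distinguished by residues at 25 canonical positions, by a cysteine cluster
with CXXCXC topography at positions 124–129 (CENCDC in betaIII), by a serine
rather than the easily oxidised cysteine at position 239, and by a C-terminal
tail that ends in a basic residue and carries landmark residues M436, Y437
and S444. Because some invertebrate beta-tubulins (notably in cephalopods)
independently carry subsets of these features, counting how many signature
positions an arbitrary beta-tubulin shares with betaIII is a simple,
reproducible way to quantify that resemblance. tubsig implements this
counting machinery, the motif calls, the tail profiling, and a classifier
for tumour-derived substitutions that converge on betaIII residues.

## Canonical numbering

All positions are 1-based coordinates on human betaIII (450 residues). Every
input sequence is placed on this coordinate system by pairwise global
alignment against the bundled reference (`build_numbering_map()`):
Needleman–Wunsch with BLOSUM62, gap opening 10, gap extension 0.5, as
implemented in Biostrings. Aligned non-gap columns become (query index,
canonical position) pairs; query residues opposite reference gaps are
recorded as insertion blocks; reference positions opposite query gaps become
unmapped canonical positions. Beta-tubulins are typically more than 90%
identical over the core, so any reasonable alignment scheme reproduces the
same correspondence; what matters is determinism, and the aligner's
tie-breaking is deterministic for fixed parameters. Known insertion cases —
some insect beta-tubulins carry 5–6 extra residues in the 55–60 region — are
handled by the same mechanism and verified by property tests.

Two numerical choices deserve mention:

* **Homology floor.** If alignment identity (matching columns over aligned
  non-gap columns) falls below 40%, numbering is refused: canonical
  coordinates on a non-homolog are meaningless. The floor is a guard against
  garbage input, not a biological threshold, and is configurable.
* **Degenerate insertion placement.** When an insertion block is spliced
  immediately adjacent to residues that themselves differ from the
  reference, gap placement can be genuinely ambiguous — any aligner may
  swap inserted letters with mismatching planted neighbours at equal score.
  Real tubulin insertions sit in otherwise conserved context, where
  placement is unambiguous; the synthetic tests exercise that situation.

### The bundled reference is synthetic

The package cannot ship the database record for human betaIII, so the
bundled reference (`betaIII_reference_synthetic.fasta`) is a constructed
stand-in: every residue documented in the transcribed tables is exact (all
25 signature positions, hexamer 124–129, tetramer 237–240, C354, and the
complete 26-residue tail), and the remaining positions follow the human
TUBB3 consensus. No quantity the package reports depends on the
unconstrained positions; they only provide realistic alignment context.

## The signature scheme

`signature_scheme()` carries the ordered 25 positions, per-isotype reference
residues from the vertebrate comparison table, and three curated subsets:

* `universal8` = {35, 56, 84, 124, 189, 239, 275, 351}: conserved in every
  vertebrate betaIII examined and distinct from the betaI/betaII/betaIV
  isotypes.
* `betaV12` = {37, 55, 56, 91, 124, 239, 315, 332, 333, 335, 351, 365}: the
  positions at which human betaV carries the betaIII residue.
* `cancer_mutated17`: the 17 signature positions observed mutated in
  breast-tumour beta-tubulins.

`universal8` and `betaV12` are shipped as constants rather than recomputed,
because their original derivation drew on many vertebrate sequences that are
not part of the printed matrices. The general classifier
(`conserved_distinct_positions()`) is provided so users can recompute such
sets on their own sequence collections; applied to the six vertebrate
betaIII columns against the five non-betaIII human isotypes of the bundled
matrix it returns a 13-position superset of `universal8`, exactly as
expected from the narrower input.

Match semantics are plain identity of uppercase one-letter codes; `X` and
absent residues never match. Each fixture table keeps its own printed
betaIII column as the comparison reference — the tables disagree at position
189 (I in the vertebrate table, L in the invertebrate table), and the
published match counts are only reproducible against the column as printed.
The printed match-count columns themselves are retained in the motif fixture
as provenance but are never used in computation; a handful of printed rows
are internally inconsistent with their own residue matrices, and the package
reports only recomputed counts.

## Motifs and the C-terminal tail

The cysteine cluster call is anchored: the hexamer is read at canonical
124–129 and the cluster is present exactly when cysteines occupy 124, 127
and 129 (the CXXCXC topography). A free-scanning motif search is
deliberately out of scope — the biology is positional. The position-239
neighbourhood is reported as the 237–240 tetramer; the window is inferred
from the printed context strings (TTSL/TTCL with S/C at the third place) —
the source never states it explicitly.

The C-terminal tail is taken as canonical 425 to the end. The tables'
footnotes put the excluded C-terminal region approximately at "431-", but
every printed tail begins YQDAT and the betaIII truncation experiment
(removal of the last 21 of 450 residues leaves YQDAT as the new terminus)
places that pentamer at 425–429; 425 reconciles the two and is the package
default (`tail_start`, configurable). Tail features are overall
characteristics, not per-position identities: length, terminal residue and
its basicity (basic = K or R only, following the observed vertebrate betaIII
termini; histidine is not counted), acidic residue count (D + E), and the
landmark flags M436/Y437/S444. When a numbering map is available the
landmarks are read at canonical coordinates, so indels elsewhere in the
sequence do not shift them; for tail-only input they are read by direct
offset from `tail_start`.

## Mutation classification

A substitution event (isotype, canonical position, reference residue,
observed residue) is `toward_betaIII` when the position is one of the 25 and
the observed residue equals the betaIII residue there; `no_change` when
observed equals reference; `off_signature` outside the 25 positions
(including the entire C-terminal region, which the underlying tumour survey
excluded); `other_substitution` otherwise. Summaries are pure tallies —
per-position counts, distinct positions, overlaps with `universal8` and
`betaV12`, grade and chemotherapy breakdowns. No association statistics are
computed: the source evidence is qualitative (e.g. all C239 substitutions
other than C→S occurred with low-grade tumours) and reports no per-arm
denominators, so a test statistic would suggest precision the data do not
support. The bundled mutation table is synthetic: it encodes the three
published patient mutation lists with betaIVB reference residues, but
sample-level grade/chemotherapy fields are placeholders.

## The synthetic-data generator

`generate_record()` derives test sequences from the reference: residues
planted at chosen canonical positions (typically a fixture column),
insertion blocks of configurable length, i.i.d. substitution noise, and an
optional replacement tail. By default noise is confined to core positions
that are neither signature nor motif positions, so the ground-truth manifest
computed at generation time — planted residues, match counts over the three
subsets, cluster call, tetramer, tail features — must be recovered exactly
by the pipeline; this exact-recovery property is what the cohort tests
assert (50 records across five spec templates, which runs in seconds). A
`noisy_signature_rate` mode flips signature residues with stated probability
for robustness testing, with the manifest updated to match. Substitution
noise is i.i.d. over positions by design; no phylogenetic substitution model
is emulated. Randomness uses one master seed with per-record derived seeds,
so a cohort is byte-reproducible from its seed.

What passing these tests shows — and does not show. The generator emulates
the features the pipeline measures: high core identity, localized indels,
planted signature states, variable tails. It does not emulate rate
heterogeneity, composition bias, or genuinely divergent families, so
synthetic recovery demonstrates correctness of the coordinate and counting
machinery, not robustness to arbitrary real-world divergence. The fixture
regressions against the published matrices are the complementary check on
real sequence data.

## Known limitations

* Numbering is strictly pairwise against a single reference; no multiple
  alignment is constructed, and queries more divergent than ~40% identity
  are refused rather than numbered.
* The 3D-structure placements of the signature positions are carried as
  annotation text only; no structural computation is performed.
* Convergence counts are raw tallies; the package deliberately provides no
  permutation null or significance machinery.
* The printed source tables contain a few internally inconsistent rows;
  these are preserved as printed but excluded from every asserted
  expectation.
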