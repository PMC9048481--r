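Package: tubsig
Title: Beta-Tubulin Isotype Signature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the residue signature that distinguishes the
    neuronal beta-III tubulin isotype from the other vertebrate beta-tubulins.
    Maps beta-tubulin amino-acid sequences onto the canonical human beta-III
    numbering by pairwise global alignment, extracts residues at the 25
    signature positions, detects the CXXCXC cysteine cluster at positions
    124-129 and the serine/cysteine state at position 239, scores resemblance
    of arbitrary sequences to beta-III and beta-V reference sets, profiles the
    hypervariable C-terminal tail, and classifies amino-acid substitutions
    observed in tumours as convergent toward beta-III. Bundles the published
    residue matrices and C-terminal tails as plain-text fixtures, and includes
    a seeded generator of tubulin-like synthetic sequences with ground-truth
    manifests for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
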