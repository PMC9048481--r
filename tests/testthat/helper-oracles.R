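# Brute-force oracles kept independent of the package implementation:
# plain position-by-position loops over named residue vectors.

oracle_match_count <- function(res_a, res_b, positions) {
  n <- 0L
  for (p in as.character(positions)) {
    a <- res_a[[p]]
    b <- res_b[[p]]
    if (!is.na(a) && !is.na(b) && a != "X" && b != "X" && a == b) n <- n + 1L
  }
  n
}

oracle_identical_positions <- function(res_a, res_b, positions) {
  out <- integer(0)
  for (p in positions) {
    a <- res_a[[as.character(p)]]
    b <- res_b[[as.character(p)]]
    if (!is.na(a) && !is.na(b) && a != "X" && b != "X" && a == b) {
      out <- c(out, p)
    }
  }
  sort(out)
}

oracle_cluster_present <- function(hexamer) {
  grepl("^C..C.C$", hexamer)
}

random_profile <- function(id, positions) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  residue_profile(id, setNames(sample(aa, length(positions), replace = TRUE),
                               positions))
}

all_profile_positions <- function() {
  sort(unique(c(signature_scheme()$positions,
                125L, 127L, 128L, 129L, 237L, 238L, 240L)))
}
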