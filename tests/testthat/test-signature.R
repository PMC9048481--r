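test_that("the signature scheme carries 25 positions and coherent subsets", {
  sch <- signature_scheme()
  expect_length(sch$positions, 25L)
  expect_length(sch$subsets$universal8, 8L)
  expect_length(sch$subsets$betaV12, 12L)
  expect_length(sch$subsets$cancer_mutated17, 17L)
  for (s in sch$subsets) expect_true(all(s %in% sch$positions))
  for (p in sch$profiles) {
    expect_true(all(as.character(sch$positions) %in% names(profile_residues(p))))
  }
})

test_that("fixture matrices load with expected shape and spot-checked residues", {
  t3 <- load_fixture_matrix("table3")
  expect_length(t3$profiles, 18L)  # betaIII reference + 17 taxa
  expect_equal(profile_residues(t3$profiles$Ob)[["124"]], "C")
  expect_equal(profile_residues(t3$profiles$betaIII)[["189"]], "L")

  t1 <- load_fixture_matrix("table1")
  expect_equal(profile_residues(t1$profiles$Hs_bI)[["239"]], "C")
  expect_equal(profile_residues(t1$profiles$Hs_bIII)[["239"]], "S")

  # motif residues merged from the motif fixture
  expect_equal(unname(profile_residues(t3$profiles$Ob)[as.character(124:129)]),
               c("C", "E", "G", "C", "E", "C"))
})

test_that("profiles extracted from full-length sequences match direct reads", {
  sch <- signature_scheme()
  ref <- reference_record()
  nm <- build_numbering_map(ref$residues)
  prof <- extract_profile(ref, nm, sch)
  expect_equal(profile_residues(prof)[["239"]], "S")
  expect_equal(profile_residues(prof)[["124"]], "C")
  expect_equal(profile_residues(prof)[["126"]], "N")
  expect_equal(match_count(prof, sch$profiles$betaIII), 25L)

  short <- substr(ref$residues, 1, 100)
  prof2 <- extract_profile(short, build_numbering_map(short), sch)
  res2 <- profile_residues(prof2)
  expect_true(all(is.na(res2[as.integer(names(res2)) >= 124])))
})

test_that("match counting agrees with a brute-force oracle on random profiles", {
  set.seed(404)
  sch <- signature_scheme()
  pos <- all_profile_positions()
  ref <- sch$profiles$betaIII
  for (i in 1:200) {
    p <- random_profile(paste0("r", i), pos)
    sub <- sample(list(sch$positions, sch$subsets$universal8,
                       sch$subsets$betaV12, sch$subsets$cancer_mutated17), 1)[[1]]
    expect_identical(match_count(p, ref, sub),
                     oracle_match_count(profile_residues(p),
                                        profile_residues(ref), sub))
    expect_identical(match_count(p, ref, sub),
                     length(identical_positions(p, ref, sub)))
  }
})

test_that("match counts are bounded and self-comparison saturates", {
  set.seed(77)
  sch <- signature_scheme()
  for (i in 1:20) {
    p <- random_profile(paste0("b", i), sch$positions)
    n <- match_count(p, sch$profiles$betaIII, sch$subsets$betaV12)
    expect_gte(n, 0L)
    expect_lte(n, 12L)
    expect_equal(match_count(p, p, sch$subsets$betaV12), 12L)
    expect_equal(match_count(p, p, sch$positions), 25L)
  }
})

test_that("identical_positions matches the oracle and handles disjoint alphabets", {
  set.seed(55)
  pos <- signature_scheme()$positions
  for (i in 1:50) {
    a <- random_profile("a", pos)
    b <- random_profile("b", pos)
    expect_identical(identical_positions(a, b, pos),
                     oracle_identical_positions(profile_residues(a),
                                                profile_residues(b), pos))
  }
  a <- residue_profile("a", setNames(rep("A", 25), pos))
  b <- residue_profile("b", setNames(rep("G", 25), pos))
  expect_length(identical_positions(a, b, pos), 0L)
})

test_that("conserved-distinct classification reproduces the table-derived sets", {
  sch <- signature_scheme()
  t1 <- load_fixture_matrix("table1")
  contrast <- t1$profiles[c("Hs_bI", "Hs_bIIA", "Hs_bIIB", "Hs_bIVA", "Hs_bIVB")]

  # human betaIII alone vs the five other human isotypes: distinct everywhere
  # except 48 (shared with betaI), 335 (shared with betaIVA) and 364
  # (shared with betaIIA/betaIIB)
  got <- conserved_distinct_positions(list(t1$profiles$Hs_bIII), contrast)
  expect_equal(got, setdiff(sch$positions, c(48L, 335L, 364L)))

  # six vertebrate betaIII columns vs the same contrast
  focal <- t1$profiles[c("Hs_bIII", "Mm_bIII", "Gg_bIII", "Gj_bIII",
                         "Xl_bIII", "Ss_bIII")]
  got6 <- conserved_distinct_positions(focal, contrast)
  expect_equal(got6, c(35L, 55L, 56L, 84L, 91L, 124L, 126L, 189L, 239L,
                       275L, 332L, 333L, 351L))

  # focal == contrast yields nothing under strict_all
  expect_length(conserved_distinct_positions(contrast, contrast), 0L)
})

test_that("conserved-distinct output is order-invariant and strict_all nests in majority", {
  set.seed(99)
  pos <- signature_scheme()$positions
  for (i in 1:10) {
    focal <- lapply(1:3, function(j) random_profile(paste0("f", j), pos))
    contrast <- lapply(1:4, function(j) random_profile(paste0("c", j), pos))
    strict <- conserved_distinct_positions(focal, contrast, pos, "strict_all")
    maj <- conserved_distinct_positions(focal, contrast, pos, "majority")
    expect_true(all(strict %in% maj))
    perm <- conserved_distinct_positions(rev(focal), sample(contrast), pos,
                                         "strict_all")
    expect_identical(strict, perm)
  }
})

test_that("missing fixture rows raise an integrity error", {
  # a fixture with a dropped position row must not load silently
  tab <- read.delim(system.file("extdata", "table1_vertebrate_isotypes.tsv",
                                package = "tubsig"))
  expect_true(all(signature_scheme()$positions %in% tab$position))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab[tab$position != 239, ], f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(tubsig:::read_fixture_table(f), "missing signature position")
})
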