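test_that("a no-op spec reproduces the reference exactly", {
  gr <- generate_record(synthetic_spec(seed = 42))
  expect_identical(gr$record$residues, reference_record()$residues)
  expect_equal(gr$manifest$match_all25, 25L)
  expect_equal(gr$manifest$cluster_hexamer, "CENCDC")
  expect_equal(gr$manifest$region239, "TTSL")
  expect_true(gr$manifest$terminal_basic)
})

test_that("planting a fixture column yields that column's published counts", {
  t3 <- load_fixture_matrix("table3")
  ob <- profile_residues(t3$profiles$Ob)
  gr <- generate_record(synthetic_spec(planted_profile = ob, seed = 7))
  # expected counts in the manifest are vs the vertebrate-table betaIII
  # column (I189), while the invertebrate table prints L189; the planted Ob
  # column matches 7 positions under both references
  expect_equal(gr$manifest$match_all25, 7L)
  expect_equal(gr$manifest$match_betaV12, 4L)
  expect_equal(gr$manifest$match_universal8, 3L)
  expect_true(gr$manifest$cluster_present)
  expect_equal(gr$manifest$cluster_hexamer, "CEGCEC")
})

test_that("invalid planted residues and rates are rejected", {
  expect_error(synthetic_spec(planted_profile = c("124" = "Z")), "valid amino-acid")
  expect_error(synthetic_spec(substitution_rate = 1.5))
  expect_error(synthetic_spec(insertions = data.frame(after_position = 10,
                                                      length = 0)))
})

test_that("substitution noise lands within the binomial envelope", {
  # eligible sites: core positions 1-424 minus the 35 protected
  # signature/motif positions
  n_eligible <- 424L - length(tubsig:::protected_positions())
  rate <- 0.05
  lo <- qbinom(0.005, n_eligible, rate)
  hi <- qbinom(0.995, n_eligible, rate)
  ref <- reference_record()$residues
  set.seed(1)
  for (i in 1:20) {
    gr <- generate_record(synthetic_spec(substitution_rate = rate,
                                         seed = 1000 + i))
    d <- sum(strsplit(gr$record$residues, "")[[1]] != strsplit(ref, "")[[1]])
    expect_gte(d, lo)
    expect_lte(d, hi)
  }
})

test_that("cohorts are seed-reproducible byte for byte", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  m1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  m2 <- withr::local_tempfile(fileext = ".tsv")
  spec <- synthetic_spec(substitution_rate = 0.02)
  generate_cohort(5, spec, seed = 99, fasta = f1, manifest = m1)
  generate_cohort(5, spec, seed = 99, fasta = f2, manifest = m2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(m1), readLines(m2))

  one <- generate_cohort(1, spec, seed = 99)
  five <- generate_cohort(5, spec, seed = 99)
  expect_identical(one$records$residues, five$records$residues[1])
})

test_that("the pipeline recovers every manifest value on a mixed cohort", {
  sch <- signature_scheme()
  t3 <- load_fixture_matrix("table3")
  specs <- list(
    synthetic_spec(substitution_rate = 0.02),
    synthetic_spec(planted_profile = profile_residues(t3$profiles$Ob),
                   substitution_rate = 0.02),
    synthetic_spec(planted_profile = profile_residues(t3$profiles$So1),
                   insertions = data.frame(after_position = 60, length = 5),
                   substitution_rate = 0.02),
    synthetic_spec(tail = "YQDATAEEEGEF", substitution_rate = 0.02)
  )
  cohort <- generate_cohort(12, specs, seed = 17)
  ref_res <- reference_record()$residues
  for (i in seq_len(nrow(cohort$records))) {
    rec <- cohort$records[i, , drop = FALSE]
    man <- cohort$manifest[i, , drop = FALSE]
    nm <- build_numbering_map(rec$residues, ref_res)
    prof <- extract_profile(rec, nm, sch)
    expect_identical(profile_residues(prof),
                     profile_residues(manifest_profile(man)))
    expect_equal(match_count(prof, sch$profiles$betaIII), man$match_all25)
    expect_equal(match_count(prof, sch$profiles$betaIII, sch$subsets$betaV12),
                 man$match_betaV12)
    cl <- call_cluster(prof)
    expect_equal(cl$present, man$cluster_present)
    expect_equal(cl$hexamer, man$cluster_hexamer)
    st <- split_tail(rec, nm)
    expect_equal(st$tail, man$tail)
    expect_equal(cterminal_features(st$tail)$terminal_basic,
                 man$terminal_basic)
  }
})

test_that("insertions of length 1-10 at random sites never disturb the planted profile", {
  set.seed(2024)
  sch <- signature_scheme()
  ref_res <- reference_record()$residues
  t1 <- load_fixture_matrix("table1")
  planted <- profile_residues(t1$profiles$Hs_bV)[as.character(sch$positions)]
  sites <- sample(setdiff(30:400, tubsig:::protected_positions()), 20)
  for (k in seq_along(sites)) {
    len <- sample(1:10, 1)
    gr <- generate_record(synthetic_spec(
      planted_profile = planted,
      insertions = data.frame(after_position = sites[k], length = len),
      seed = 3000 + k))
    nm <- build_numbering_map(gr$record$residues, ref_res)
    got <- residue_at(gr$record, nm, sch$positions)
    expect_equal(unname(got), unname(planted),
                 info = sprintf("insertion of %d after %d", len, sites[k]))
  }
})

test_that("signature noise mode updates the manifest consistently", {
  sch <- signature_scheme()
  ref_res <- reference_record()$residues
  gr <- generate_record(synthetic_spec(noisy_signature_rate = 0.3, seed = 8))
  nm <- build_numbering_map(gr$record$residues, ref_res)
  prof <- extract_profile(gr$record, nm, sch)
  expect_identical(profile_residues(prof),
                   profile_residues(manifest_profile(gr$manifest)))
  expect_equal(match_count(prof, sch$profiles$betaIII), gr$manifest$match_all25)
})
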