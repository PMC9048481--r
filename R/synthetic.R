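AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Specification for one synthetic tubulin-like sequence
#'
#' Describes how to derive a test sequence from the bundled canonical
#' reference: residues planted at chosen canonical positions, insertion
#' blocks spliced after chosen positions (emulating the 5-6-residue
#' insertions seen in the 55-60 region of some insect beta-tubulins),
#' i.i.d. substitution noise confined by default to non-signature,
#' non-motif core positions, and an optional replacement C-terminal tail.
#'
#' @param planted_profile Named character vector of residues to impose
#'   (names are canonical positions), e.g. a fixture column.
#' @param insertions Data frame with columns \code{after_position} and
#'   \code{length} (lengths >= 1); may be \code{NULL}.
#' @param substitution_rate Per-position substitution probability in
#'   \code{[0, 1]}, applied only at core positions that are neither
#'   signature nor motif positions (so manifest counts stay exact).
#' @param tail Optional replacement tail string (canonical 425 onward).
#' @param noisy_signature_rate Probability of flipping each signature/motif
#'   residue to a random different residue (robustness testing; the
#'   manifest is updated accordingly). Default 0.
#' @param seed Integer seed for this record.
#' @return An object of class \code{SyntheticSpec}.
#' @export
synthetic_spec <- function(planted_profile = NULL, insertions = NULL,
                           substitution_rate = 0, tail = NULL,
                           noisy_signature_rate = 0, seed = 1L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            noisy_signature_rate >= 0, noisy_signature_rate <= 1)
  if (!is.null(planted_profile)) {
    stopifnot(is.character(planted_profile), !is.null(names(planted_profile)))
    bad <- !planted_profile %in% AA_ALPHABET
    if (any(bad)) {
      stop("planted residue(s) not valid amino-acid letters: ",
           paste(unique(planted_profile[bad]), collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(insertions)) {
    stopifnot(is.data.frame(insertions),
              all(c("after_position", "length") %in% names(insertions)),
              all(insertions$length >= 1L),
              all(insertions$after_position >= 0L))
  }
  structure(list(planted_profile = planted_profile, insertions = insertions,
                 substitution_rate = substitution_rate, tail = tail,
                 noisy_signature_rate = noisy_signature_rate,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

protected_positions <- function() {
  sort(unique(c(SIGNATURE_POSITIONS, 124:129, 237:240)))
}

#' Generate one synthetic record with its ground-truth manifest entry
#'
#' Derives a sequence from the canonical reference per the supplied generator
#' specification object and computes,
#' at generation time, what the pipeline is expected to recover from it:
#' the residues at every signature and motif position, match counts against
#' the beta-III reference over the three standard subsets, the cysteine
#' cluster call, the 237-240 tetramer, and the tail features.
#'
#' @param spec A [synthetic_spec()].
#' @param id Record id (default \code{"syn1"}).
#' @param scheme A [signature_scheme()].
#' @return A list with \code{record} (single-row record data frame) and
#'   \code{manifest} (single-row data frame of expected values; the
#'   \code{profile} column serializes planted residues as
#'   \code{"pos=res;..."}).
#' @examples
#' gr <- generate_record(synthetic_spec(seed = 42))
#' identical(gr$record$residues, reference_record()$residues)
#' @export
generate_record <- function(spec, id = "syn1", scheme = signature_scheme()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  ref <- strsplit(reference_record()$residues, "")[[1L]]
  core_len <- 424L
  res <- ref

  # planted residues on canonical coordinates
  if (!is.null(spec$planted_profile)) {
    pos <- as.integer(names(spec$planted_profile))
    stopifnot(all(pos >= 1L), all(pos <= length(res)))
    res[pos] <- spec$planted_profile
  }

  # optional signature-position noise (manifest reflects the flips)
  protected <- protected_positions()
  if (spec$noisy_signature_rate > 0) {
    flip <- protected[stats::runif(length(protected)) < spec$noisy_signature_rate]
    for (p in flip) {
      res[p] <- sample(setdiff(AA_ALPHABET, res[p]), 1L)
    }
  }

  # i.i.d. substitution noise at unconstrained core positions
  if (spec$substitution_rate > 0) {
    eligible <- setdiff(seq_len(core_len), protected)
    if (!is.null(spec$planted_profile)) {
      eligible <- setdiff(eligible, as.integer(names(spec$planted_profile)))
    }
    hit <- eligible[stats::runif(length(eligible)) < spec$substitution_rate]
    for (p in hit) {
      res[p] <- sample(setdiff(AA_ALPHABET, res[p]), 1L)
    }
  }

  # replacement tail
  tail_str <- if (!is.null(spec$tail)) toupper(spec$tail) else
    paste(res[(core_len + 1L):length(res)], collapse = "")
  canonical <- res  # canonical-coordinate residues, before insertions

  # expected values, computed from canonical coordinates at generation time
  prof_pos <- sort(unique(c(scheme$positions, MOTIF_POSITIONS)))
  profile <- residue_profile(id, stats::setNames(canonical[prof_pos], prof_pos))
  ref_profile <- scheme$profiles$betaIII
  cl <- call_cluster(profile)
  feats <- cterminal_features(tail_str)
  manifest <- data.frame(
    id = id,
    seed = spec$seed,
    profile = paste(sprintf("%d=%s", prof_pos, canonical[prof_pos]),
                    collapse = ";"),
    match_all25 = match_count(profile, ref_profile, scheme$positions),
    match_betaV12 = match_count(profile, ref_profile, scheme$subsets$betaV12),
    match_universal8 = match_count(profile, ref_profile,
                                   scheme$subsets$universal8),
    cluster_present = cl$present,
    cluster_hexamer = cl$hexamer,
    region239 = region239(profile),
    tail = tail_str,
    terminal_basic = feats$terminal_basic,
    acidic_count = feats$acidic_count,
    stringsAsFactors = FALSE
  )

  # assemble the residue string: core + insertions + tail
  seq_chars <- c(res[seq_len(core_len)], strsplit(tail_str, "")[[1L]])
  if (!is.null(spec$insertions) && nrow(spec$insertions) > 0L) {
    ins <- spec$insertions[order(-spec$insertions$after_position), , drop = FALSE]
    for (j in seq_len(nrow(ins))) {
      at <- ins$after_position[j]
      block <- sample(AA_ALPHABET, ins$length[j], replace = TRUE)
      seq_chars <- append(seq_chars, block, after = at)
    }
  }

  record <- data.frame(
    id = id, species = "synthetic", isotype_label = "synthetic",
    description = sprintf("synthetic tubulin-like sequence (seed %d)", spec$seed),
    residues = paste(seq_chars, collapse = ""),
    stringsAsFactors = FALSE
  )
  list(record = record, manifest = manifest)
}

#' Generate a synthetic cohort with FASTA and manifest outputs
#'
#' Generates \code{n} records from one spec (or a list of specs recycled
#' across records), with per-record seeds derived deterministically from the
#' master seed so the same master seed reproduces byte-identical files.
#'
#' @param n Number of records (>= 1).
#' @param spec A [synthetic_spec()] or list of them (recycled).
#' @param seed Master integer seed.
#' @param fasta,manifest Optional output paths; written as FASTA and TSV
#'   when given.
#' @param scheme A [signature_scheme()].
#' @return A list with \code{records} (data frame) and \code{manifest}
#'   (data frame, one row per record).
#' @export
generate_cohort <- function(n, spec = synthetic_spec(), seed = 1L,
                            fasta = NULL, manifest = NULL,
                            scheme = signature_scheme()) {
  stopifnot(n >= 1L)
  specs <- if (inherits(spec, "SyntheticSpec")) list(spec) else spec
  stopifnot(all(vapply(specs, inherits, logical(1), "SyntheticSpec")))
  out_rec <- vector("list", n)
  out_man <- vector("list", n)
  for (i in seq_len(n)) {
    s <- specs[[((i - 1L) %% length(specs)) + 1L]]
    s$seed <- as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)
    gr <- generate_record(s, id = sprintf("syn%03d", i), scheme = scheme)
    out_rec[[i]] <- gr$record
    out_man[[i]] <- gr$manifest
  }
  records <- do.call(rbind, out_rec)
  man <- do.call(rbind, out_man)
  if (!is.null(fasta)) write_fasta(records, fasta)
  if (!is.null(manifest)) {
    utils::write.table(man, manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(records = records, manifest = man)
}

#' Parse a serialized manifest profile back into a ResidueProfile
#'
#' @param manifest_row One row of a cohort manifest.
#' @return A \code{ResidueProfile}.
#' @export
manifest_profile <- function(manifest_row) {
  parts <- strsplit(strsplit(manifest_row$profile, ";")[[1L]], "=")
  residue_profile(manifest_row$id,
                  stats::setNames(vapply(parts, `[`, character(1), 2L),
                                  vapply(parts, `[`, character(1), 1L)))
}
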