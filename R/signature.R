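# The 25 canonical positions at which beta-III differs from most other
# vertebrate beta isotypes while being conserved across vertebrate beta-III.
SIGNATURE_POSITIONS <- c(33L, 35L, 37L, 48L, 55L, 56L, 57L, 80L, 83L, 84L,
                         91L, 124L, 126L, 155L, 189L, 218L, 239L, 275L, 315L,
                         332L, 333L, 335L, 351L, 364L, 365L)

# Motif positions read alongside the signature: the cysteine-cluster window
# 124-129 and the position-239 neighbourhood 237-240 (124, 126 and 239 are
# already signature positions).
MOTIF_POSITIONS <- c(125L, 127L, 128L, 129L, 237L, 238L, 240L)

#' The beta-III signature scheme
#'
#' Returns the ordered 25 canonical signature positions together with the
#' per-isotype reference residues (from the vertebrate isotype comparison
#' table), the named position subsets used throughout the package, and
#' per-position annotation.
#'
#' Subsets:
#' \describe{
#'   \item{universal8}{\{35, 56, 84, 124, 189, 239, 275, 351\} — conserved in
#'     every vertebrate beta-III examined and distinct from the
#'     betaI/betaII/betaIV isotypes.}
#'   \item{betaV12}{\{37, 55, 56, 91, 124, 239, 315, 332, 333, 335, 351,
#'     365\} — the positions where human betaV carries the beta-III residue.}
#'   \item{cancer_mutated17}{\{33, 35, 48, 124, 126, 155, 189, 218, 239, 275,
#'     315, 332, 333, 335, 351, 364, 365\} — signature positions mutated in
#'     breast-tumour beta-tubulins.}
#' }
#'
#' @return An object of class \code{SignatureScheme}: list with
#'   \code{positions}, \code{profiles} (named list of
#'   \code{ResidueProfile}s, including \code{HMBG_betaIII}, the profile
#'   shared by human/mouse/bovine/chicken beta-III), \code{subsets},
#'   \code{structure_note} and \code{chemo} annotations.
#' @examples
#' sch <- signature_scheme()
#' length(sch$positions)
#' subset_overlap(sch$subsets$universal8, sch$subsets$cancer_mutated17)
#' @export
signature_scheme <- function() {
  tab1 <- read_fixture_table("table1_vertebrate_isotypes.tsv")
  iso_cols <- c(betaIII = "Hs_bIII", betaI = "Hs_bI", betaIIA = "Hs_bIIA",
                betaIIB = "Hs_bIIB", betaIVA = "Hs_bIVA", betaIVB = "Hs_bIVB",
                betaV = "Hs_bV", betaVI = "Hs_bVI")
  profiles <- lapply(seq_along(iso_cols), function(i) {
    residue_profile(names(iso_cols)[i],
                    stats::setNames(tab1[[iso_cols[i]]], tab1$position))
  })
  names(profiles) <- names(iso_cols)
  # human, mouse, bovine and chicken beta-III are identical at these positions
  profiles$HMBG_betaIII <- residue_profile(
    "HMBG_betaIII", stats::setNames(tab1$Hs_bIII, tab1$position))

  structure_note <- stats::setNames(c(
    "H1/S2 loop", "H1/S2 loop", "H1/S2 loop", "H1/S2 loop", "H1/S2 loop",
    "H1/S2 loop", "H1/S2 loop", "H2/S3 loop", "H2/S3 loop", "H2/S3 loop",
    "beta-sheet S3", "alpha-helix H3", "H3/S4 loop", "alpha-helix H4",
    "alpha-helix H5", "H6/H7 loop", "H7/H8 loop", "S7/H9 loop",
    "beta-sheet S8", "alpha-helix H10", "alpha-helix H10", "alpha-helix H10",
    "beta-sheet S9", "beta-sheet S10", "beta-sheet S10"),
    SIGNATURE_POSITIONS)
  chemo <- stats::setNames(c(
    "t", "t", "", "n", "", "", "", "", "", "", "", "t", "t", "n,t", "t", "t",
    "t", "n", "n", "n,d", "n,d", "n,d", "n,d", "", "n,d"),
    SIGNATURE_POSITIONS)

  structure(list(
    positions = SIGNATURE_POSITIONS,
    profiles = profiles,
    subsets = list(
      universal8 = c(35L, 56L, 84L, 124L, 189L, 239L, 275L, 351L),
      betaV12 = c(37L, 55L, 56L, 91L, 124L, 239L, 315L, 332L, 333L, 335L,
                  351L, 365L),
      cancer_mutated17 = c(33L, 35L, 48L, 124L, 126L, 155L, 189L, 218L, 239L,
                           275L, 315L, 332L, 333L, 335L, 351L, 364L, 365L)
    ),
    structure_note = structure_note,
    chemo = chemo
  ), class = "SignatureScheme")
}

#' @export
print.SignatureScheme <- function(x, ...) {
  cat(sprintf("SignatureScheme: %d positions, %d reference profiles, subsets: %s\n",
              length(x$positions), length(x$profiles),
              paste(sprintf("%s(%d)", names(x$subsets),
                            lengths(x$subsets)), collapse = ", ")))
  invisible(x)
}

#' Construct a residue profile
#'
#' A \code{ResidueProfile} stores one sequence's residues at canonical
#' positions (the 25 signature positions, optionally plus motif positions
#' 125, 127-129 and 237-240). Absent positions are \code{NA}.
#'
#' @param sequence_id Label for the sequence.
#' @param residues Named character vector: names are canonical positions,
#'   values single uppercase residue letters (or \code{NA}).
#' @return An object of class \code{ResidueProfile}.
#' @export
residue_profile <- function(sequence_id, residues) {
  stopifnot(is.character(residues), !is.null(names(residues)))
  pos <- as.integer(names(residues))
  stopifnot(!anyNA(pos), !anyDuplicated(pos))
  bad <- !is.na(residues) & !grepl("^[A-Z]$", residues)
  if (any(bad)) {
    stop("invalid residue letter(s) at position(s) ",
         paste(pos[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(sequence_id = as.character(sequence_id),
                 residues = stats::setNames(as.character(residues), pos)),
            class = "ResidueProfile")
}

#' @export
print.ResidueProfile <- function(x, ...) {
  cat(sprintf("ResidueProfile '%s' (%d positions)\n", x$sequence_id,
              length(x$residues)))
  print(x$residues)
  invisible(x)
}

profile_residue <- function(profile, positions) {
  out <- profile$residues[as.character(positions)]
  stats::setNames(unname(out), positions)
}

read_fixture_table <- function(file) {
  path <- if (file.exists(file)) file else tubsig_extdata(file)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  tab$position <- as.integer(tab$position)
  missing <- setdiff(SIGNATURE_POSITIONS, tab$position)
  if (length(missing)) {
    stop("fixture ", file, " is missing signature position(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab[match(SIGNATURE_POSITIONS, tab$position), , drop = FALSE]
}

#' Load a bundled residue-matrix fixture
#'
#' Loads one of the transcribed comparison tables as residue profiles over
#' the 25 signature positions. Where the bundled motif table documents a
#' taxon's 124-129 hexamer and 237-240 tetramer, those residues are merged
#' into the profile (after an integrity check against the matrix itself).
#'
#' @param table_name One of \code{"table1"} (vertebrate isotypes),
#'   \code{"table2"} (beta-VI isotypes) or \code{"table3"} (non-vertebrate
#'   beta-tubulins).
#' @return A list with \code{profiles} (named list of
#'   \code{ResidueProfile}s), \code{reference} (that table's beta-III
#'   reference profile) and \code{motifs} (the motif annotation rows for the
#'   table, including the printed match-count columns, which are carried as
#'   provenance and never recomputed from).
#' @examples
#' fx <- load_fixture_matrix("table3")
#' profile_residues(fx$profiles$Ob)[["124"]]
#' @export
load_fixture_matrix <- function(table_name) {
  table_name <- match.arg(table_name, c("table1", "table2", "table3"))
  file <- switch(table_name,
                 table1 = "table1_vertebrate_isotypes.tsv",
                 table2 = "table2_betaVI_isotypes.tsv",
                 table3 = "table3_invertebrates.tsv")
  tab <- read_fixture_table(file)
  taxa <- setdiff(names(tab), "position")
  profiles <- lapply(taxa, function(cl) {
    residue_profile(cl, stats::setNames(tab[[cl]], tab$position))
  })
  names(profiles) <- taxa

  motifs <- utils::read.delim(tubsig_extdata("table5_motifs.tsv"),
                              stringsAsFactors = FALSE)
  motifs <- motifs[motifs$table == table_name, , drop = FALSE]
  for (j in seq_len(nrow(motifs))) {
    cl <- motifs$column[j]
    if (!cl %in% names(profiles)) next
    profiles[[cl]] <- merge_motif_residues(
      profiles[[cl]], motifs$hexamer[j], motifs$region239[j], file)
  }

  ref_col <- switch(table_name, table1 = "Hs_bIII", table2 = "Hs_bIII",
                    table3 = "betaIII")
  list(profiles = profiles, reference = profiles[[ref_col]], motifs = motifs)
}

merge_motif_residues <- function(profile, hexamer, tetramer, file) {
  res <- profile$residues
  add <- character(0)
  if (!is.na(hexamer) && nzchar(hexamer)) {
    if (nchar(hexamer) != 6L) {
      stop("fixture integrity error in ", file, ": hexamer '", hexamer,
           "' for ", profile$sequence_id, " is not 6 letters", call. = FALSE)
    }
    hx <- stats::setNames(strsplit(hexamer, "")[[1L]], 124:129)
    check_motif_agreement(res, hx, profile$sequence_id, file)
    add <- c(add, hx)
  }
  if (!is.na(tetramer) && nzchar(tetramer) && tetramer != "NA") {
    if (nchar(tetramer) != 4L) {
      stop("fixture integrity error in ", file, ": tetramer '", tetramer,
           "' for ", profile$sequence_id, " is not 4 letters", call. = FALSE)
    }
    tt <- stats::setNames(strsplit(tetramer, "")[[1L]], 237:240)
    check_motif_agreement(res, tt, profile$sequence_id, file)
    add <- c(add, tt)
  }
  if (length(add)) {
    keep <- setdiff(names(add), names(res))
    res <- c(res, add[keep])
    res <- res[order(as.integer(names(res)))]
  }
  residue_profile(profile$sequence_id, res)
}

check_motif_agreement <- function(res, motif, id, file) {
  shared <- intersect(names(res), names(motif))
  bad <- shared[res[shared] != motif[shared]]
  if (length(bad)) {
    stop("fixture integrity error: motif residues for '", id, "' disagree ",
         "with the residue matrix at position(s) ",
         paste(bad, collapse = ", "), " (", file, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Residues of a profile as a named vector
#'
#' @param profile A \code{ResidueProfile}.
#' @return Named character vector (names are canonical positions).
#' @export
profile_residues <- function(profile) {
  stopifnot(inherits(profile, "ResidueProfile"))
  profile$residues
}

#' Extract a residue profile from a sequence
#'
#' Reads the query residues at the 25 signature positions plus the motif
#' positions (124-129 and 237-240) through its numbering map.
#'
#' @inheritParams residue_at
#' @param scheme A [signature_scheme()] (defaults to the bundled scheme).
#' @return A \code{ResidueProfile}; unmapped positions are \code{NA}.
#' @export
extract_profile <- function(record, map, scheme = signature_scheme()) {
  positions <- sort(unique(c(scheme$positions, MOTIF_POSITIONS)))
  res <- residue_at(record, map, positions)
  id <- if (is.data.frame(record)) record$id else "query"
  residue_profile(id, stats::setNames(res, positions))
}

#' Count signature-position matches against a reference profile
#'
#' Counts the positions in \code{subset} at which the profile carries a
#' residue that is present and identical to the reference residue. Absent
#' residues and \code{X} never match.
#'
#' @param profile,reference_profile \code{ResidueProfile}s.
#' @param subset Integer vector of canonical positions (defaults to all 25
#'   signature positions).
#' @return Integer match count.
#' @examples
#' fx <- load_fixture_matrix("table3")
#' match_count(fx$profiles$Ob, fx$reference)  # 7
#' @export
match_count <- function(profile, reference_profile,
                        subset = SIGNATURE_POSITIONS) {
  length(identical_positions(profile, reference_profile, subset))
}

#' Positions at which two profiles carry the same residue
#'
#' @param profile_a,profile_b \code{ResidueProfile}s.
#' @param positions Canonical positions to compare (default: the 25
#'   signature positions).
#' @return Sorted integer vector of positions where both residues are
#'   present, not \code{X}, and identical.
#' @examples
#' sch <- signature_scheme()
#' identical_positions(sch$profiles$betaV, sch$profiles$betaIII)  # 12 positions
#' @export
identical_positions <- function(profile_a, profile_b,
                                positions = SIGNATURE_POSITIONS) {
  a <- profile_residue(profile_a, positions)
  b <- profile_residue(profile_b, positions)
  ok <- !is.na(a) & !is.na(b) & a != "X" & b != "X" & a == b
  sort(as.integer(positions[ok]))
}

#' Positions conserved within a focal set and distinct from a contrast set
#'
#' Finds positions where (a) every focal profile carries the same residue,
#' and (b) that residue differs from the residue of every contrast profile
#' (\code{rule = "strict_all"}) or from more than half of them
#' (\code{rule = "majority"}). Positions where any focal residue is absent
#' are never reported; absent contrast residues count as differing.
#'
#' @param focal,contrast Non-empty lists of \code{ResidueProfile}s.
#' @param positions Canonical positions to consider.
#' @param rule \code{"strict_all"} or \code{"majority"}.
#' @return Sorted integer vector of positions.
#' @export
conserved_distinct_positions <- function(focal, contrast,
                                         positions = SIGNATURE_POSITIONS,
                                         rule = c("strict_all", "majority")) {
  rule <- match.arg(rule)
  stopifnot(length(focal) > 0L, length(contrast) > 0L)
  if (inherits(focal, "ResidueProfile")) focal <- list(focal)
  if (inherits(contrast, "ResidueProfile")) contrast <- list(contrast)
  keep <- vapply(positions, function(p) {
    fr <- vapply(focal, function(pr) profile_residue(pr, p), character(1))
    if (anyNA(fr) || any(fr == "X") || length(unique(fr)) != 1L) return(FALSE)
    r <- fr[[1L]]
    cr <- vapply(contrast, function(pr) profile_residue(pr, p), character(1))
    differs <- is.na(cr) | cr != r
    if (rule == "strict_all") all(differs) else sum(differs) > length(cr) / 2
  }, logical(1))
  sort(as.integer(positions[keep]))
}

#' Size of the intersection of two position sets
#'
#' @param set_a,set_b Integer vectors of canonical positions.
#' @return Integer, the number of shared positions.
#' @export
subset_overlap <- function(set_a, set_b) {
  length(intersect(as.integer(set_a), as.integer(set_b)))
}
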