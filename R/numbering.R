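#' Read amino-acid sequences from a FASTA file
#'
#' Parses a (multi-record) FASTA file into a data frame of sequence records.
#' The header token before the first whitespace becomes the record id; the
#' remainder of the header is kept as the description. An isotype label such
#' as \code{betaIII} is picked out of the description when present.
#'
#' @param path Path to a FASTA-formatted file of amino-acid sequences.
#' @return A data frame with one row per record and columns \code{id},
#'   \code{species}, \code{isotype_label}, \code{description} and
#'   \code{residues} (uppercase amino-acid string). An empty file yields a
#'   zero-row data frame.
#' @examples
#' ref <- read_fasta(system.file("extdata", "betaIII_reference_synthetic.fasta",
#'                               package = "tubsig"))
#' nchar(ref$residues)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(empty_records())
  }
  if (!startsWith(trimws(lines[[1L]]), ">")) {
    stop("malformed FASTA: first non-empty line is not a header (line 1)",
         call. = FALSE)
  }
  # pre-scan for illegal residue characters so errors can name the line
  raw <- readLines(path, warn = FALSE)
  for (i in seq_along(raw)) {
    ln <- trimws(raw[[i]])
    if (!nzchar(ln) || startsWith(ln, ">")) next
    if (grepl("[^A-Za-z]", ln)) {
      stop("illegal character in sequence at line ", i, ": '", ln, "'",
           call. = FALSE)
    }
  }
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  desc <- sub("^\\S+\\s*", "", headers)
  residues <- toupper(as.character(aa))
  empty <- !nzchar(residues)
  if (any(empty)) {
    stop("empty sequence for record: ", paste(ids[empty], collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    id = ids,
    species = extract_species(desc),
    isotype_label = extract_isotype(desc),
    description = desc,
    residues = residues,
    stringsAsFactors = FALSE
  )
}

empty_records <- function() {
  data.frame(id = character(), species = character(),
             isotype_label = character(), description = character(),
             residues = character(), stringsAsFactors = FALSE)
}

extract_species <- function(desc) {
  sp <- regmatches(desc, regexpr("\\[[^]]+\\]", desc))
  out <- character(length(desc))
  has <- grepl("\\[[^]]+\\]", desc)
  out[has] <- gsub("^\\[|\\]$", "", regmatches(desc, regexpr("\\[[^]]+\\]", desc)))
  out
}

extract_isotype <- function(desc) {
  m <- regexpr("beta[IVX]+[AB]?", desc, ignore.case = TRUE)
  out <- rep("unknown", length(desc))
  hit <- m > 0
  out[hit] <- tolower(regmatches(desc, m))
  out
}

#' Write sequence records to a FASTA file
#'
#' @param records Data frame of records as returned by [read_fasta()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  aa <- Biostrings::AAStringSet(records$residues)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(aa) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(aa, filepath = path, width = 60L)
  invisible(path)
}

#' Load the bundled canonical beta-III reference sequence
#'
#' The reference fixes the canonical 1-based numbering (450 residues). It is
#' a synthetic stand-in for the human beta-III sequence: residues at all
#' documented positions are exact, the remainder follow the TUBB3 consensus.
#'
#' @return A single-row record data frame (see [read_fasta()]).
#' @export
reference_record <- function() {
  read_fasta(tubsig_extdata("betaIII_reference_synthetic.fasta"))
}

#' Build a canonical numbering map by pairwise global alignment
#'
#' Aligns a query amino-acid sequence to the canonical reference (Needleman-
#' Wunsch, BLOSUM62, affine gaps) and converts the alignment into a
#' correspondence between 1-based query indices and canonical positions.
#' Query residues aligned to reference gaps are recorded as insertions;
#' reference positions aligned to query gaps become unmapped canonical
#' positions.
#'
#' @param query Amino-acid string (or single-row record data frame).
#' @param reference Amino-acid string; defaults to the bundled canonical
#'   reference.
#' @param min_identity Identity floor (fraction of matching aligned columns,
#'   gaps excluded) below which the query is rejected as a non-homolog and
#'   canonical numbering would be meaningless. Default 0.4.
#' @return An object of class \code{NumberingMap}: a list with elements
#'   \code{pairs} (data frame \code{seq_index}, \code{canonical}),
#'   \code{insertions} (data frame \code{after_canonical}, \code{length}),
#'   \code{unmapped_canonical} (integer vector), \code{identity},
#'   \code{query_length} and \code{ref_length}.
#' @examples
#' ref <- reference_record()
#' nm <- build_numbering_map(ref$residues)
#' nrow(nm$pairs)  # identity map: 450 pairs
#' @export
build_numbering_map <- function(query, reference = NULL, min_identity = 0.4) {
  query <- as_residue_string(query)
  if (is.null(reference)) reference <- reference_record()$residues
  reference <- as_residue_string(reference)
  stopifnot(nzchar(query), nzchar(reference))

  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(reference),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5,
    type = "global"
  )
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  identity <- if (nm + nmm > 0) nm / (nm + nmm) else 0
  if (identity < min_identity) {
    stop(sprintf(
      "query is not a recognisable homolog of the reference (identity %.1f%% < floor %.1f%%)",
      100 * identity, 100 * min_identity), call. = FALSE)
  }

  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  stopifnot(length(qa) == length(ra))

  qi <- 0L; ri <- 0L
  seq_index <- integer(0); canonical <- integer(0)
  ins_after <- integer(0); ins_len <- integer(0)
  unmapped <- integer(0)
  pending_ins <- 0L
  for (k in seq_along(qa)) {
    qgap <- qa[k] == "-"; rgap <- ra[k] == "-"
    if (!qgap && !rgap) {
      if (pending_ins > 0L) {
        ins_after <- c(ins_after, ri); ins_len <- c(ins_len, pending_ins)
        pending_ins <- 0L
      }
      qi <- qi + 1L; ri <- ri + 1L
      seq_index <- c(seq_index, qi); canonical <- c(canonical, ri)
    } else if (!qgap && rgap) {
      qi <- qi + 1L
      pending_ins <- pending_ins + 1L
    } else if (qgap && !rgap) {
      if (pending_ins > 0L) {
        ins_after <- c(ins_after, ri); ins_len <- c(ins_len, pending_ins)
        pending_ins <- 0L
      }
      ri <- ri + 1L
      unmapped <- c(unmapped, ri)
    }
  }
  if (pending_ins > 0L) {
    ins_after <- c(ins_after, ri); ins_len <- c(ins_len, pending_ins)
  }

  structure(list(
    pairs = data.frame(seq_index = seq_index, canonical = canonical),
    insertions = data.frame(after_canonical = ins_after, length = ins_len),
    unmapped_canonical = unmapped,
    identity = identity,
    query_length = nchar(query),
    ref_length = nchar(reference)
  ), class = "NumberingMap")
}

#' @export
print.NumberingMap <- function(x, ...) {
  cat(sprintf("NumberingMap: %d/%d query residues mapped onto canonical 1-%d\n",
              nrow(x$pairs), x$query_length, x$ref_length))
  cat(sprintf("  identity %.1f%%; %d insertion block(s); %d unmapped canonical position(s)\n",
              100 * x$identity, nrow(x$insertions), length(x$unmapped_canonical)))
  invisible(x)
}

as_residue_string <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("residues" %in% names(x), nrow(x) == 1L)
    x <- x$residues
  }
  toupper(as.character(x))
}

#' Residue of a query sequence at a canonical position
#'
#' @param record Record data frame row or plain residue string the map was
#'   built for.
#' @param map A [build_numbering_map()] result for that sequence.
#' @param canonical_position Integer vector of canonical positions (1-based).
#' @return Character vector of residue letters, \code{NA} where the canonical
#'   position is not mapped in the query.
#' @export
residue_at <- function(record, map, canonical_position) {
  stopifnot(inherits(map, "NumberingMap"))
  canonical_position <- as.integer(canonical_position)
  if (any(canonical_position < 1L)) {
    stop("canonical positions must be >= 1", call. = FALSE)
  }
  residues <- as_residue_string(record)
  idx <- map$pairs$seq_index[match(canonical_position, map$pairs$canonical)]
  out <- rep(NA_character_, length(canonical_position))
  ok <- !is.na(idx)
  if (any(ok)) out[ok] <- substring(residues, idx[ok], idx[ok])
  out
}

#' Split a sequence into its core and C-terminal tail
#'
#' The tail is the hypervariable C-terminal region, canonical positions
#' \code{tail_start} (default 425) through the end of the query, including
#' any insertion residues falling beyond the boundary. The core is the
#' remainder; core and tail concatenate back to the original sequence.
#'
#' @inheritParams residue_at
#' @param tail_start First canonical position of the tail (default 425).
#' @return A list with elements \code{core} and \code{tail} (strings).
#' @examples
#' ref <- reference_record()
#' nm <- build_numbering_map(ref$residues)
#' split_tail(ref, nm)$tail
#' @export
split_tail <- function(record, map, tail_start = 425L) {
  stopifnot(inherits(map, "NumberingMap"), tail_start >= 1L)
  residues <- as_residue_string(record)
  n <- nchar(residues)
  cand <- map$pairs$seq_index[map$pairs$canonical >= tail_start]
  if (nrow(map$insertions) > 0L) {
    ins <- map$insertions[map$insertions$after_canonical >= tail_start, , drop = FALSE]
    if (nrow(ins) > 0L) {
      # first query index of an insertion block after canonical c is one past
      # the query index paired with c (or with the last mapped position <= c)
      for (j in seq_len(nrow(ins))) {
        before <- map$pairs$seq_index[map$pairs$canonical <= ins$after_canonical[j]]
        start <- if (length(before)) max(before) + 1L else 1L
        cand <- c(cand, start)
      }
    }
  }
  if (length(cand) == 0L) {
    return(list(core = residues, tail = ""))
  }
  t0 <- min(cand)
  list(core = substr(residues, 1L, t0 - 1L), tail = substr(residues, t0, n))
}

#' Export a numbering map as a tab-separated table
#'
#' @param map A \code{NumberingMap}.
#' @param path Output path for a two-column TSV (\code{seq_index},
#'   \code{canonical}).
#' @return Invisibly, \code{path}.
#' @export
export_numbering <- function(map, path) {
  stopifnot(inherits(map, "NumberingMap"))
  utils::write.table(map$pairs, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
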