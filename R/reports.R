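#' Signature match report (machine twin of the published comparison rows)
#'
#' For each input sequence or fixture column, reports the match counts
#' against the beta-III reference over the full 25-position signature, the
#' betaV-12 subset and the universal-8 subset, plus the cysteine-cluster
#' call (Yes/No and hexamer) and the 237-240 tetramer.
#'
#' @param records Record data frame (see [read_fasta()]); sequences are
#'   numbered against the canonical reference and profiled. Mutually
#'   exclusive with \code{fixture}.
#' @param fixture Name of a bundled residue matrix (\code{"table1"},
#'   \code{"table2"}, \code{"table3"}); its columns are profiled directly
#'   and compared against that table's own printed beta-III column.
#' @param reference Optional \code{ResidueProfile} to compare against
#'   (default: the fixture's own beta-III column, or the scheme's beta-III
#'   profile for FASTA input).
#' @param scheme A [signature_scheme()].
#' @param min_identity Homology floor passed to [build_numbering_map()].
#' @return Data frame with one row per sequence: \code{id},
#'   \code{match_all25}, \code{match_betaV12}, \code{match_universal8},
#'   \code{cluster} ("Yes"/"No"), \code{hexamer}, \code{region239}.
#' @examples
#' compare_report(fixture = "table3")["Ob", ]  # 7 / 4 / 3, Yes (CEGCEC)
#' @export
compare_report <- function(records = NULL, fixture = NULL, reference = NULL,
                           scheme = signature_scheme(), min_identity = 0.4) {
  if (is.null(records) == is.null(fixture)) {
    stop("supply exactly one of 'records' or 'fixture'", call. = FALSE)
  }
  if (!is.null(fixture)) {
    fx <- load_fixture_matrix(fixture)
    profiles <- fx$profiles
    if (is.null(reference)) reference <- fx$reference
  } else {
    if (nrow(records) == 0L) {
      return(data.frame(id = character(), match_all25 = integer(),
                        match_betaV12 = integer(), match_universal8 = integer(),
                        cluster = character(), hexamer = character(),
                        region239 = character(), stringsAsFactors = FALSE))
    }
    ref_res <- reference_record()$residues
    profiles <- lapply(seq_len(nrow(records)), function(i) {
      rec <- records[i, , drop = FALSE]
      nm <- build_numbering_map(rec$residues, ref_res,
                                min_identity = min_identity)
      extract_profile(rec, nm, scheme)
    })
    names(profiles) <- records$id
    if (is.null(reference)) reference <- scheme$profiles$betaIII
  }
  rows <- lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    cl <- call_cluster(p)
    data.frame(
      id = id,
      match_all25 = match_count(p, reference, scheme$positions),
      match_betaV12 = match_count(p, reference, scheme$subsets$betaV12),
      match_universal8 = match_count(p, reference, scheme$subsets$universal8),
      cluster = if (cl$present) "Yes" else "No",
      hexamer = cl$hexamer,
      region239 = region239(p),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$id
  out
}

#' C-terminal tail feature report
#'
#' @param records Record data frame; tails are extracted through numbering
#'   maps against the canonical reference. Mutually exclusive with
#'   \code{tails}.
#' @param tails Data frame with columns \code{label} and \code{tail}
#'   (e.g. [load_tail_fixture()]); features are computed by direct indexing
#'   from \code{tail_start}.
#' @param tail_start First canonical tail position (default 425).
#' @return Data frame with one row per sequence: \code{id}, \code{tail},
#'   \code{length}, \code{terminal_residue}, \code{terminal_basic},
#'   \code{acidic_count}, \code{has_M436}, \code{has_Y437}, \code{has_S444}.
#' @export
ctermini_report <- function(records = NULL, tails = NULL, tail_start = 425L) {
  if (is.null(records) == is.null(tails)) {
    stop("supply exactly one of 'records' or 'tails'", call. = FALSE)
  }
  feats_row <- function(id, f) {
    data.frame(id = id, tail = f$tail, length = f$length,
               terminal_residue = ifelse(is.na(f$terminal_residue), "-",
                                         f$terminal_residue),
               terminal_basic = f$terminal_basic,
               acidic_count = f$acidic_count, has_M436 = f$has_M436,
               has_Y437 = f$has_Y437, has_S444 = f$has_S444,
               stringsAsFactors = FALSE)
  }
  if (!is.null(tails)) {
    stopifnot(all(c("label", "tail") %in% names(tails)))
    rows <- lapply(seq_len(nrow(tails)), function(i) {
      feats_row(tails$label[i],
                cterminal_features(tails$tail[i], tail_start = tail_start))
    })
  } else {
    if (nrow(records) == 0L) rows <- list() else {
      ref_res <- reference_record()$residues
      rows <- lapply(seq_len(nrow(records)), function(i) {
        rec <- records[i, , drop = FALSE]
        nm <- build_numbering_map(rec$residues, ref_res)
        st <- split_tail(rec, nm, tail_start = tail_start)
        feats_row(rec$id, cterminal_features(st$tail, map = nm, record = rec,
                                             tail_start = tail_start))
      })
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(id = character(), tail = character(),
                      length = integer(), terminal_residue = character(),
                      terminal_basic = logical(), acidic_count = integer(),
                      has_M436 = logical(), has_Y437 = logical(),
                      has_S444 = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mutation summary report
#'
#' Classifies events and returns the per-position toward-beta-III tally as a
#' data frame, suitable for writing as TSV.
#'
#' @inheritParams classify_mutations
#' @return A list with \code{events} (classified events), \code{summary}
#'   (see [summarize_events()]) and \code{per_position} (data frame
#'   \code{position}, \code{n_toward}).
#' @export
mutation_report <- function(events, scheme = signature_scheme()) {
  events <- classify_mutations(events, scheme)
  s <- summarize_events(events, scheme)
  per_position <- data.frame(position = as.integer(names(s$per_position)),
                             n_toward = unname(s$per_position))
  list(events = events, summary = s, per_position = per_position)
}

#' Write a report table atomically as TSV
#'
#' Writes to a temporary file in the target directory and renames, so a
#' failed run never leaves a partial output behind.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.table(x, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) {
    stop("could not move report into place: ", path, call. = FALSE)
  }
  invisible(path)
}

resolve_input <- function(config) {
  has_input <- !is.null(config$input)
  has_fixture <- !is.null(config$fixture)
  if (has_input == has_fixture) {
    stop("config must name exactly one input source ('input' or 'fixture')",
         call. = FALSE)
  }
  config
}

#' Run the signature comparison pipeline from a configuration
#'
#' @param config A list with exactly one of \code{input} (FASTA path) or
#'   \code{fixture} (\code{"table1"}/\code{"table2"}/\code{"table3"}), and
#'   optionally \code{out} (TSV path) and \code{min_identity}.
#' @return The report data frame (invisibly when written to \code{out}).
#' @export
run_compare <- function(config) {
  config <- resolve_input(config)
  rep <- if (!is.null(config$fixture)) {
    compare_report(fixture = config$fixture)
  } else {
    compare_report(records = read_fasta(config$input),
                   min_identity = config$min_identity %||% 0.4)
  }
  if (!is.null(config$out)) {
    write_report(rep, config$out)
    return(invisible(rep))
  }
  rep
}

#' Run the C-terminal feature pipeline from a configuration
#'
#' @param config A list with exactly one of \code{input} (FASTA path) or
#'   \code{fixture} (\code{"table4"}), and optionally \code{out} and
#'   \code{tail_start}.
#' @return The report data frame (invisibly when written to \code{out}).
#' @export
run_ctermini <- function(config) {
  config <- resolve_input(config)
  tail_start <- config$tail_start %||% 425L
  rep <- if (!is.null(config$fixture)) {
    if (!identical(config$fixture, "table4")) {
      stop("ctermini supports the 'table4' fixture", call. = FALSE)
    }
    ctermini_report(tails = load_tail_fixture(), tail_start = tail_start)
  } else {
    ctermini_report(records = read_fasta(config$input),
                    tail_start = tail_start)
  }
  if (!is.null(config$out)) {
    write_report(rep, config$out)
    return(invisible(rep))
  }
  rep
}

#' Run the mutation classification pipeline from a configuration
#'
#' @param config A list with \code{input} (mutation TSV path; \code{NULL}
#'   for the bundled synthetic table) and optionally \code{out}.
#' @return The [mutation_report()] list (invisibly when written).
#' @export
run_mutations <- function(config) {
  events <- read_mutation_events(config$input)
  rep <- mutation_report(events)
  if (!is.null(config$out)) {
    write_report(rep$events, config$out)
    return(invisible(rep))
  }
  rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a
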