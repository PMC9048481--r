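MUTATION_ISOTYPES <- c("betaI", "betaIIA", "betaIIB", "betaIVA", "betaIVB")

#' Read a mutation-event table
#'
#' Events arrive pre-called as a tab-separated file with columns
#' \code{sample_id}, \code{isotype}, \code{position}, \code{ref}, \code{obs},
#' \code{grade}, \code{chemo}.
#'
#' @param path Path to the TSV; defaults to the bundled synthetic table
#'   modeled on the published breast-tumour patient lists.
#' @return Data frame of events.
#' @export
read_mutation_events <- function(path = NULL) {
  if (is.null(path)) path <- tubsig_extdata("cancer_mutations_synthetic.tsv")
  ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "isotype", "position", "ref", "obs", "grade", "chemo")
  missing <- setdiff(need, names(ev))
  if (length(missing)) {
    stop("mutation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ev$position <- as.integer(ev$position)
  ev$ref <- toupper(ev$ref)
  ev$obs <- toupper(ev$obs)
  ev
}

#' Classify amino-acid substitutions relative to the beta-III signature
#'
#' A substitution in a non-beta-III isotype is \emph{toward-beta-III}
#' (convergent) when its position is one of the 25 signature positions and
#' the observed residue equals the beta-III residue there. Events at
#' positions outside the signature (including anything in the C-terminal
#' region, which the underlying survey excluded) are \code{off_signature};
#' observed equal to reference is \code{no_change}; everything else is
#' \code{other_substitution}.
#'
#' @param events Data frame of events (see [read_mutation_events()]).
#' @param scheme A [signature_scheme()].
#' @return The events data frame with an added factor column
#'   \code{classification} with levels \code{toward_betaIII},
#'   \code{other_substitution}, \code{no_change}, \code{off_signature}.
#' @examples
#' ev <- data.frame(sample_id = "s", isotype = "betaIVB", position = 239,
#'                  ref = "C", obs = "S", grade = "high", chemo = "unknown")
#' classify_mutations(ev)$classification  # toward_betaIII
#' @export
classify_mutations <- function(events, scheme = signature_scheme()) {
  stopifnot(is.data.frame(events))
  lv <- c("toward_betaIII", "other_substitution", "no_change", "off_signature")
  if (nrow(events) == 0L) {
    events$classification <- factor(character(), levels = lv)
    return(events)
  }
  bad_iso <- setdiff(unique(events$isotype), MUTATION_ISOTYPES)
  if (length(bad_iso)) {
    stop("isotype label(s) not covered by the scheme: ",
         paste(bad_iso, collapse = ", "), call. = FALSE)
  }
  b3 <- profile_residues(scheme$profiles$betaIII)
  cls <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    p <- events$position[i]
    if (!p %in% scheme$positions) {
      cls[i] <- "off_signature"
    } else if (events$obs[i] == events$ref[i]) {
      cls[i] <- "no_change"
    } else if (events$obs[i] == b3[[as.character(p)]]) {
      cls[i] <- "toward_betaIII"
    } else {
      cls[i] <- "other_substitution"
    }
  }
  events$classification <- factor(cls, levels = lv)
  events
}

#' Summarize classified mutation events
#'
#' Pure tallies, mirroring how the source survey reported them: per-position
#' toward-beta-III counts, distinct positions hit, overlap of those positions
#' with the universal-8 and betaV-12 subsets, and breakdowns by grade and
#' chemotherapy annotation. No association statistics are computed.
#'
#' @inheritParams classify_mutations
#' @return A list with \code{n_events}, \code{n_toward},
#'   \code{toward_positions}, \code{per_position} (named integer vector of
#'   toward-beta-III counts), \code{n_distinct_positions},
#'   \code{overlap_universal8}, \code{overlap_betaV12},
#'   \code{by_classification}, \code{by_grade} and \code{by_chemo} tables.
#' @export
summarize_events <- function(events, scheme = signature_scheme()) {
  if (!"classification" %in% names(events)) {
    events <- classify_mutations(events, scheme)
  }
  toward <- events[events$classification == "toward_betaIII", , drop = FALSE]
  pos <- sort(unique(toward$position))
  per_position <- if (nrow(toward)) {
    tab <- table(factor(toward$position, levels = pos))
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  list(
    n_events = nrow(events),
    n_toward = nrow(toward),
    toward_positions = as.integer(pos),
    per_position = per_position,
    n_distinct_positions = length(pos),
    overlap_universal8 = subset_overlap(pos, scheme$subsets$universal8),
    overlap_betaV12 = subset_overlap(pos, scheme$subsets$betaV12),
    by_classification = table(events$classification),
    by_grade = if (nrow(events)) table(events$grade, events$classification)
               else table(character(), character()),
    by_chemo = if (nrow(events)) table(events$chemo, events$classification)
               else table(character(), character())
  )
}
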