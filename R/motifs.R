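#' Call the cysteine cluster at canonical positions 124-129
#'
#' The cluster is the CXXCXC arrangement (cysteines at canonical 124, 127
#' and 129; CENCDC in human beta-III). Detection is anchored at those
#' canonical positions, not scanned along the sequence: the motif is
#' positional.
#'
#' @param profile A \code{ResidueProfile} covering positions 124-129 (absent
#'   positions are rendered as \code{-} in the hexamer and defeat the call).
#' @return A list with \code{present} (logical) and \code{hexamer}
#'   (six-character string for positions 124-129).
#' @examples
#' sch <- signature_scheme()
#' fx <- load_fixture_matrix("table1")
#' call_cluster(fx$profiles$Hs_bIII)  # TRUE, "CENCDC"
#' @export
call_cluster <- function(profile) {
  res <- profile_residue(profile, 124:129)
  res[is.na(res)] <- "-"
  hexamer <- paste(res, collapse = "")
  present <- res[[1L]] == "C" && res[[4L]] == "C" && res[[6L]] == "C"
  list(present = present, hexamer = hexamer)
}

#' The position-239 neighbourhood (canonical 237-240)
#'
#' Serine versus cysteine at 239 separates beta-III/betaV/betaVI (and fungi)
#' from almost all other eukaryotic beta-tubulins; the tetramer gives its
#' immediate context (TTSL in human beta-III, TTCL in human beta-I).
#'
#' @param profile A \code{ResidueProfile} covering positions 237-240.
#' @return Four-character string, \code{-} for absent positions.
#' @export
region239 <- function(profile) {
  res <- profile_residue(profile, 237:240)
  res[is.na(res)] <- "-"
  paste(res, collapse = "")
}

#' C-terminal tail features
#'
#' Computes the composition features by which beta-III tails are recognised:
#' terminal basicity (vertebrate beta-III tails always end in lysine or
#' arginine), acidic-residue count, and the landmark residues M436, Y437 and
#' S444. When a numbering map and the full sequence are supplied the
#' landmarks are read at their canonical positions (robust to indels in the
#' tail); otherwise the tail is indexed directly from \code{tail_start}.
#'
#' @param tail Tail string as returned by [split_tail()] (may be empty).
#' @param map Optional \code{NumberingMap} for the sequence the tail came
#'   from.
#' @param record Optional record (or residue string) the map was built for;
#'   required when \code{map} is given.
#' @param tail_start Canonical position at which the tail begins (default
#'   425); used for direct indexing when no map is supplied.
#' @return A list with \code{tail}, \code{length}, \code{terminal_residue},
#'   \code{terminal_basic}, \code{acidic_count}, \code{has_M436},
#'   \code{has_Y437} and \code{has_S444}.
#' @examples
#' cterminal_features("YQDATAEEEGEMYEDDEEESEAQGPK")
#' @export
cterminal_features <- function(tail, map = NULL, record = NULL,
                               tail_start = 425L) {
  tail <- toupper(as.character(tail))
  n <- nchar(tail)
  if (n == 0L) {
    return(list(tail = "", length = 0L, terminal_residue = NA_character_,
                terminal_basic = FALSE, acidic_count = 0L,
                has_M436 = FALSE, has_Y437 = FALSE, has_S444 = FALSE))
  }
  letters_vec <- strsplit(tail, "")[[1L]]
  terminal <- letters_vec[n]
  acidic <- sum(letters_vec %in% c("D", "E"))

  landmark <- function(pos, letter) {
    if (!is.null(map)) {
      if (is.null(record)) {
        stop("record must be supplied alongside map", call. = FALSE)
      }
      r <- residue_at(record, map, pos)
      !is.na(r) && r == letter
    } else {
      off <- pos - tail_start + 1L
      off >= 1L && off <= n && letters_vec[off] == letter
    }
  }

  list(
    tail = tail,
    length = n,
    terminal_residue = terminal,
    terminal_basic = terminal %in% c("K", "R"),
    acidic_count = as.integer(acidic),
    has_M436 = landmark(436L, "M"),
    has_Y437 = landmark(437L, "Y"),
    has_S444 = landmark(444L, "S")
  )
}

#' Load the bundled C-terminal tail fixture
#'
#' The transcribed C-terminal regions of the surveyed beta-tubulins:
#' vertebrate beta-III tails, the other human isotypes, cephalopod and other
#' mollusk tubulins, further invertebrates, and representative other
#' eukaryotes.
#'
#' @return Data frame with columns \code{group}, \code{label}, \code{tail}.
#' @export
load_tail_fixture <- function() {
  utils::read.delim(tubsig_extdata("table4_ctermini.tsv"),
                    stringsAsFactors = FALSE)
}
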