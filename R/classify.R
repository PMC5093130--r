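#' Proline content and terminal-flank metrics
#'
#' Counts prolines and reports whether a Pro flanks each terminus.
#' Pro-rich 8C hevein-like peptides carry 3-6 Pro with Pro at both ends
#' (gB5: positions 2, 14, 33, 41 of 41), a feature tied to exopeptidase
#' resistance. "Flanking" is operationalised as a Pro within the first
#' \code{n_window} residues (default 3, accepting gB5's P2) and within
#' the last \code{c_window} residues (default 2, accepting the ...CP
#' terminus).
#'
#' @param seq Peptide string.
#' @param n_window,c_window Terminal window sizes in residues.
#' @return List of class \code{pro_metrics}: \code{count},
#'   \code{positions} (1-based), \code{n_flank}, \code{c_flank},
#'   \code{n_window}, \code{c_window}.
#' @export
pro_metrics <- function(seq, n_window = 3L, c_window = 2L) {
  seq <- check_peptide(seq)
  pos <- which(seq_chars(seq) == "P")
  n <- nchar(seq)
  structure(list(
    count = length(pos), positions = pos,
    n_flank = any(pos <= n_window),
    c_flank = any(pos > n - c_window),
    n_window = as.integer(n_window), c_window = as.integer(c_window)),
    class = "pro_metrics")
}

#' Classify a peptide into hevein-like subfamilies
#'
#' Assigns the 6C/8C/10C subfamily by cysteine count and tests the
#' defining criteria of the Pro-rich 8C class: eight cysteines, a
#' chitin-binding-domain motif hit, 3-6 prolines, and Pro flanking both
#' termini. Sequences containing undetermined residues (\code{X}) are
#' returned as \code{unclassified} because an \code{X} can hide a
#' cysteine or motif anchor.
#'
#' @param seq Peptide string.
#' @param motif A \code{\link{motif_definition}} used for the motif
#'   criterion.
#' @param pro_range Allowed Pro count, inclusive (default 3..6).
#' @param n_window,c_window Pro-flank windows, see
#'   \code{\link{pro_metrics}}.
#' @return List of class \code{subfamily_call}: \code{subfamily} (one of
#'   \code{"6C","8C","10C","unclassified"}), \code{pro_rich_8C},
#'   \code{evidence} (named logicals: \code{cys_count}, \code{motif},
#'   \code{pro_count}, \code{n_flank}, \code{c_flank}), \code{n_cys},
#'   and \code{reason} for unclassified calls.
#' @examples
#' classify_subfamily(gb5_sequence)$pro_rich_8C  # TRUE
#' @export
classify_subfamily <- function(seq, motif = motif_definition(),
                               pro_range = c(3L, 6L),
                               n_window = 3L, c_window = 2L) {
  seq <- check_peptide(seq)
  if (grepl("X", seq, fixed = TRUE)) {
    return(structure(list(
      subfamily = "unclassified", pro_rich_8C = FALSE,
      evidence = c(cys_count = FALSE, motif = FALSE, pro_count = FALSE,
                   n_flank = FALSE, c_flank = FALSE),
      n_cys = NA_integer_,
      reason = "undetermined residue(s) X in sequence"),
      class = "subfamily_call"))
  }
  fw <- detect_framework(seq)
  n_cys <- length(fw$cys_positions)
  subfamily <- switch(as.character(n_cys),
                      "6" = "6C", "8" = "8C", "10" = "10C",
                      "unclassified")
  hits <- scan_chitin_motif(seq, motif)
  pm <- pro_metrics(seq, n_window, c_window)
  evidence <- c(
    cys_count = n_cys == 8L,
    motif = nrow(hits) > 0L,
    pro_count = pm$count >= pro_range[1L] && pm$count <= pro_range[2L],
    n_flank = pm$n_flank,
    c_flank = pm$c_flank)
  structure(list(
    subfamily = subfamily,
    pro_rich_8C = all(evidence),
    evidence = evidence,
    n_cys = n_cys,
    reason = if (subfamily == "unclassified") {
      paste0("cysteine count ", n_cys, " is not 6, 8 or 10")
    } else NA_character_),
    class = "subfamily_call")
}

#' @export
print.subfamily_call <- function(x, ...) {
  cat("Subfamily:", x$subfamily,
      if (isTRUE(x$pro_rich_8C)) "(Pro-rich 8C class)" else "", "\n")
  ev <- paste(names(x$evidence), ifelse(x$evidence, "yes", "no"),
              sep = "=", collapse = "  ")
  cat("  evidence:", ev, "\n")
  if (!is.na(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}
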