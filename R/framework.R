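#' Detect the cysteine framework of a peptide
#'
#' Locates all Cys residues and summarises their spacing as a framework
#' pattern string in which adjacent cysteines (distance 1) are grouped
#' without a dash, e.g. \code{"C-C-CC-C-C-C-C"} for the 8-Cys hevein
#' framework with its diagnostic CC pair at framework positions III/IV.
#' Cysteines are labelled with roman numerals I..n in sequence order.
#'
#' @param seq Peptide string.
#' @return An object of class \code{cys_framework}: a list with
#'   \code{cys_positions} (1-based), \code{pattern}, and
#'   \code{cys_labels} (named integer vector, roman labels to positions).
#' @examples
#' detect_framework(gb5_sequence)$pattern  # "C-C-CC-C-C-C-C"
#' @export
detect_framework <- function(seq) {
  seq <- check_peptide(seq)
  pos <- which(seq_chars(seq) == "C")
  pattern <- if (length(pos) == 0L) "" else {
    grp <- cumsum(c(1L, diff(pos) > 1L))
    paste(vapply(split(pos, grp), function(p) strrep("C", length(p)), ""),
          collapse = "-")
  }
  labels <- if (length(pos)) {
    stats::setNames(pos, roman_labels(length(pos)))
  } else {
    stats::setNames(integer(0), character(0))
  }
  structure(list(cys_positions = pos, pattern = pattern,
                 cys_labels = labels, sequence = seq),
            class = "cys_framework")
}

#' @export
print.cys_framework <- function(x, ...) {
  cat("Cysteine framework:", if (nchar(x$pattern)) x$pattern else "(none)",
      "\n")
  if (length(x$cys_positions)) {
    cat("  ", paste(names(x$cys_labels), x$cys_labels, sep = ":",
                    collapse = "  "), "\n")
  }
  invisible(x)
}

# Canonical 8C and 10C hevein patterns: CC pair at framework III/IV.
HEVEIN_8C_PATTERN <- "C-C-CC-C-C-C-C"
HEVEIN_10C_PATTERN <- "C-C-CC-C-C-C-C-C-C"

#' Decompose a peptide into intercysteine loops
#'
#' Splits the sequence into the N-terminal segment before CysI, the
#' backbone segments (loops) between consecutive framework cysteines,
#' and the tail after the last Cys. Loop numbering follows the hevein
#' convention: the empty segment inside the adjacent CC pair carries no
#' loop number, so for the 8C framework loop 3 runs CysIV to CysV
#' (holding the chitin-binding Ser and two aromatics), loop 4 CysV to
#' CysVI, ... and loop 7 is the tail after CysVIII. The tail is counted
#' as a numbered loop only for the 8C/10C frameworks; otherwise it is
#' reported as \code{c_term}.
#'
#' @param seq Peptide string.
#' @param framework Optional precomputed \code{cys_framework}; must be
#'   consistent with \code{seq}.
#' @return An object of class \code{loop_decomposition}: list with
#'   \code{n_term}, \code{loops} (named list by loop number),
#'   \code{c_term}, \code{segments} (all inter-Cys segments plus tail,
#'   for reconstruction), and the \code{framework}.
#' @examples
#' decompose_loops(gb5_sequence)$loops[["3"]]  # "SKFNY"
#' @export
decompose_loops <- function(seq, framework = detect_framework(seq)) {
  seq <- check_peptide(seq)
  pos <- framework$cys_positions
  if (!identical(which(seq_chars(seq) == "C"), pos)) {
    stop("framework is inconsistent with the sequence", call. = FALSE)
  }
  if (length(pos) == 0L) {
    return(structure(list(n_term = seq, loops = list(), c_term = "",
                          segments = character(0), framework = framework),
                     class = "loop_decomposition"))
  }
  n_term <- substr(seq, 1L, pos[1L] - 1L)
  k <- length(pos)
  # segments[i] = between Cys i and Cys i+1; segments[k] = tail after last Cys
  segments <- character(k)
  for (i in seq_len(k - 1L)) {
    segments[i] <- substr(seq, pos[i] + 1L, pos[i + 1L] - 1L)
  }
  segments[k] <- substr(seq, pos[k] + 1L, nchar(seq))
  tail_is_loop <- framework$pattern %in% c(HEVEIN_8C_PATTERN,
                                           HEVEIN_10C_PATTERN)
  gap_widths <- if (k > 1L) diff(pos) else integer(0)
  loops <- list()
  ln <- 0L
  for (i in seq_len(k - 1L)) {
    if (gap_widths[i] == 1L) next  # empty CC gap is unnumbered
    ln <- ln + 1L
    loops[[as.character(ln)]] <- segments[i]
  }
  c_term <- segments[k]
  if (tail_is_loop) {
    loops[[as.character(ln + 1L)]] <- c_term
    c_term <- ""
  }
  structure(list(n_term = n_term, loops = loops, c_term = c_term,
                 segments = segments, framework = framework),
            class = "loop_decomposition")
}

#' Reconstruct a sequence from its loop decomposition
#'
#' Inverse of \code{\link{decompose_loops}}: interleaves the N-terminal
#' segment, the cysteines, and the inter-Cys segments back into the
#' original sequence.
#'
#' @param decomp A \code{loop_decomposition}.
#' @return The reconstructed peptide string.
#' @export
reconstruct_sequence <- function(decomp) {
  pos <- decomp$framework$cys_positions
  if (length(pos) == 0L) return(decomp$n_term)
  paste0(decomp$n_term,
         paste(vapply(seq_along(pos), function(i) {
           paste0("C", decomp$segments[i])
         }, ""), collapse = ""))
}

#' @export
print.loop_decomposition <- function(x, ...) {
  cat("N-terminal:", if (nchar(x$n_term)) x$n_term else "(empty)", "\n")
  for (nm in names(x$loops)) {
    cat(sprintf("  loop %s: %s\n", nm,
                if (nchar(x$loops[[nm]])) x$loops[[nm]] else "(empty)"))
  }
  if (nchar(x$c_term)) cat("C-terminal:", x$c_term, "\n")
  invisible(x)
}
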