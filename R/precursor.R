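#' Construct a precursor record
#'
#' A precursor record carries the full sequence of a hevein-like peptide
#' precursor together with its three-domain partition: ER signal
#' peptide, mature hevein-like domain, and C-terminal tail.
#'
#' @param id Record id.
#' @param full_sequence Full precursor amino-acid sequence.
#' @param organism Organism label (may be empty).
#' @param signal_end,mature_end 1-based positions of the last residue of
#'   the signal and mature domains, or \code{NA} when unpartitioned.
#' @param cleavage_rule_used Free-text provenance of the partition.
#' @param description Optional description.
#' @return List of class \code{precursor_record} with derived
#'   \code{signal}, \code{mature}, \code{c_tail} substrings.
#' @export
precursor_record <- function(id, full_sequence, organism = "",
                             signal_end = NA_integer_,
                             mature_end = NA_integer_,
                             cleavage_rule_used = "annotation",
                             description = "") {
  full_sequence <- check_peptide(full_sequence, what = paste0("record ", id))
  n <- nchar(full_sequence)
  if (!is.na(signal_end) && (signal_end < 1L || signal_end >= n)) {
    stop("signal_end out of range for record ", id, call. = FALSE)
  }
  if (!is.na(mature_end) &&
      (is.na(signal_end) || mature_end <= signal_end || mature_end > n)) {
    stop("mature_end out of range for record ", id, call. = FALSE)
  }
  signal <- if (is.na(signal_end)) NA_character_ else {
    substr(full_sequence, 1L, signal_end)
  }
  mature <- if (is.na(mature_end)) NA_character_ else {
    substr(full_sequence, signal_end + 1L, mature_end)
  }
  c_tail <- if (is.na(mature_end)) NA_character_ else {
    substr(full_sequence, mature_end + 1L, n)
  }
  structure(list(id = id, organism = organism,
                 full_sequence = full_sequence,
                 signal = signal, mature = mature, c_tail = c_tail,
                 signal_end = as.integer(signal_end),
                 mature_end = as.integer(mature_end),
                 cleavage_rule_used = cleavage_rule_used,
                 description = description),
            class = "precursor_record")
}

#' @export
print.precursor_record <- function(x, ...) {
  cat("Precursor", x$id,
      if (nchar(x$organism)) paste0("[", x$organism, "]"), "\n")
  cat("  full:  ", x$full_sequence, "\n")
  cat("  signal:", if (is.na(x$signal)) "(unset)" else x$signal, "\n")
  cat("  mature:", if (is.na(x$mature)) "(unset)" else x$mature, "\n")
  cat("  c_tail:", if (is.na(x$c_tail)) "(unset)" else x$c_tail, "\n")
  invisible(x)
}

#' Partition a precursor into signal, mature and C-tail domains
#'
#' With an annotation, the given boundaries are used verbatim.
#' Otherwise a rule-based partition is applied: the signal peptide ends
#' at the first Gly immediately followed by Asp (the conserved signal
#' peptidase site of ginkgotide precursors) whose position lies in the
#' \code{window}; the mature domain then runs to the
#' \code{framework_size}-th cysteine after the signal plus
#' \code{mature_tail} residues (one residue by default, covering the
#' short post-CysVIII tail such as gB5's C-terminal Pro); the remainder
#' is the C-terminal tail. When no cleavage site is found in the window
#' the record is returned unpartitioned with a diagnostic message
#' attribute.
#'
#' @param full_sequence Full precursor sequence.
#' @param id,organism Record metadata.
#' @param annotation Optional list with \code{signal_end} and
#'   \code{mature_end} (1-based inclusive).
#' @param cleavage Length-2 character vector, the cleavage dipeptide
#'   (default \code{c("G", "D")}, cleaved between the two).
#' @param window Positions searched for the cleavage site (default
#'   15..35).
#' @param framework_size Number of mature-domain cysteines (default 8).
#' @param mature_tail Residues kept after the last framework Cys.
#' @return A \code{\link{precursor_record}}; unpartitioned records carry
#'   a \code{"diagnostic"} attribute.
#' @export
partition_domains <- function(full_sequence, id = "", organism = "",
                              annotation = NULL,
                              cleavage = c("G", "D"),
                              window = c(15L, 35L),
                              framework_size = 8L,
                              mature_tail = 1L) {
  full_sequence <- check_peptide(full_sequence,
                                 what = paste0("record ", id))
  if (!is.null(annotation)) {
    return(precursor_record(id, full_sequence, organism,
                            signal_end = annotation$signal_end,
                            mature_end = annotation$mature_end,
                            cleavage_rule_used = "annotation"))
  }
  n <- nchar(full_sequence)
  if (n < 30L) {
    stop("rule-based partitioning needs >= 30 residues", call. = FALSE)
  }
  ch <- seq_chars(full_sequence)
  rule <- paste0(cleavage[1L], "|", cleavage[2L], " rule")
  hi <- min(window[2L], n - 1L)
  site <- NA_integer_
  for (g in window[1L]:hi) {
    if (ch[g] == cleavage[1L] && ch[g + 1L] == cleavage[2L]) {
      site <- g
      break
    }
  }
  if (is.na(site)) {
    rec <- precursor_record(id, full_sequence, organism,
                            cleavage_rule_used = rule)
    attr(rec, "diagnostic") <- sprintf(
      "no %s%s cleavage site in positions %d-%d",
      cleavage[1L], cleavage[2L], window[1L], hi)
    return(rec)
  }
  cys_after <- which(ch == "C")
  cys_after <- cys_after[cys_after > site]
  if (length(cys_after) == 0L) {
    rec <- precursor_record(id, full_sequence, organism,
                            cleavage_rule_used = rule)
    attr(rec, "diagnostic") <- "no cysteines after the cleavage site"
    return(rec)
  }
  k <- min(framework_size, length(cys_after))
  mature_end <- min(cys_after[k] + mature_tail, n)
  precursor_record(id, full_sequence, organism,
                   signal_end = site, mature_end = mature_end,
                   cleavage_rule_used = rule)
}

#' Classify the C-terminal tail as cargo-free or cargo-carrying
#'
#' Ginkgotide-type precursors end in a short (about 20 aa) protein-cargo
#' free tail, while other 8C/10C hevein-like precursors carry a protein
#' cargo such as a Barwin-like protein (126 aa) or a class I chitinase
#' (254 aa). Tails shorter than the threshold are called
#' \code{cargo_free}; the boundary is half-open (a tail of exactly the
#' threshold length is \code{cargo}).
#'
#' @param precursor A \code{\link{precursor_record}} with \code{c_tail}
#'   set.
#' @param threshold Length threshold in residues (default 50).
#' @return List of class \code{cargo_call}: \code{status},
#'   \code{c_tail_length}, \code{threshold}.
#' @export
cargo_classification <- function(precursor, threshold = 50L) {
  if (is.na(precursor$c_tail)) {
    stop("c_tail is unset for record ", precursor$id, call. = FALSE)
  }
  len <- nchar(precursor$c_tail)
  structure(list(
    status = if (len < threshold) "cargo_free" else "cargo",
    c_tail_length = len, threshold = as.integer(threshold)),
    class = "cargo_call")
}
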