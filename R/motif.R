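#' Define the chitin-binding-domain motif
#'
#' The conserved chitin-binding domain of hevein-like peptides is a
#' 12-residue motif S-X-phi-X-phi-C-G-X-X-X-X-Phi spanning intercysteine
#' loops 3 and 4: a Ser, two aromatics in loop 3, the CysV/Gly pair, and
#' a third aromatic in loop 4. Literal motif statements give phi = Y or
#' W and X = small amino acid, but characterised family members carry
#' Phe at the first aromatic (gB5 F21) and non-small residues at X
#' positions (gB5 K20, hevein Q), so the defaults here are the permissive
#' aromatic set \code{{F,W,Y}} and wildcard X; \code{x_mode =
#' "strict_small"} restores the literal small-residue constraint.
#'
#' @param phi_set Residues accepted at the two loop-3 aromatic positions.
#' @param tyr_set Residues accepted at the loop-4 aromatic (position 12).
#' @param x_mode \code{"wildcard"} (any residue) or \code{"strict_small"}.
#' @param small_set The small-residue set used under strict mode.
#' @return An object of class \code{motif_definition}.
#' @export
motif_definition <- function(phi_set = c("F", "W", "Y"),
                             tyr_set = c("F", "W", "Y"),
                             x_mode = c("wildcard", "strict_small"),
                             small_set = c("G", "A", "S", "T",
                                           "C", "N", "D", "P")) {
  x_mode <- match.arg(x_mode)
  structure(list(phi_set = toupper(phi_set), tyr_set = toupper(tyr_set),
                 x_mode = x_mode, small_set = toupper(small_set),
                 length = 12L),
            class = "motif_definition")
}

# Offsets within the 12-residue window (0-based from the Ser anchor):
# S at 0, X at 1, phi at 2, X at 3, phi at 4, C at 5, G at 6,
# X at 7..10, loop-4 aromatic at 11.
motif_window_ok <- function(chars, motif) {
  x_ok <- function(ch) {
    motif$x_mode == "wildcard" || ch %in% motif$small_set
  }
  chars[1L] == "S" &&
    x_ok(chars[2L]) &&
    chars[3L] %in% motif$phi_set &&
    x_ok(chars[4L]) &&
    chars[5L] %in% motif$phi_set &&
    chars[6L] == "C" &&
    chars[7L] == "G" &&
    all(vapply(chars[8L:11L], x_ok, logical(1))) &&
    chars[12L] %in% motif$tyr_set
}

#' Scan a peptide for the chitin-binding motif
#'
#' Slides the 12-residue chitin-binding-domain window over the sequence
#' and reports every match with its anchor positions (the Ser, the two
#' loop-3 aromatics at Ser+2 and Ser+4, and the loop-4 aromatic at
#' Ser+11), all 1-based.
#'
#' @param seq Peptide string.
#' @param motif A \code{\link{motif_definition}}.
#' @return Data frame with columns \code{ser_pos}, \code{phi1_pos},
#'   \code{phi2_pos}, \code{tyr_pos}, \code{matched_window}; zero rows
#'   when the motif is absent.
#' @examples
#' scan_chitin_motif(gb5_sequence)  # single hit anchored at Ser19
#' @export
scan_chitin_motif <- function(seq, motif = motif_definition()) {
  seq <- check_peptide(seq)
  ch <- seq_chars(seq)
  n <- length(ch)
  hits <- list()
  if (n >= motif$length) {
    for (i in seq_len(n - motif$length + 1L)) {
      if (motif_window_ok(ch[i:(i + 11L)], motif)) {
        hits[[length(hits) + 1L]] <- data.frame(
          ser_pos = i, phi1_pos = i + 2L, phi2_pos = i + 4L,
          tyr_pos = i + 11L,
          matched_window = substr(seq, i, i + 11L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(ser_pos = integer(), phi1_pos = integer(),
                      phi2_pos = integer(), tyr_pos = integer(),
                      matched_window = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
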