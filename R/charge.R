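#' Ionizable-group pKa sets
#'
#' Returns a published pKa table for isoelectric-point prediction. The
#' default \code{"emboss"} set is the one used by the EMBOSS iep tool
#' (N-terminus 8.6, C-terminus 3.6; side chains C 8.5, D 3.9, E 4.1,
#' H 6.5, K 10.8, R 12.5, Y 10.1). Alternative sets can be supplied to
#' \code{\link{net_charge}} as any named numeric vector with entries
#' \code{Nterm}, \code{Cterm} and a subset of \code{C,D,E,H,K,R,Y}.
#'
#' @param name Currently \code{"emboss"}.
#' @return Named numeric vector of pKa values.
#' @export
pka_set <- function(name = c("emboss")) {
  name <- match.arg(name)
  c(Nterm = 8.6, Cterm = 3.6,
    C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminal amine, the C-terminal
#' carboxyl, and the D/E/C/Y (acidic) and H/K/R (basic) side chains.
#' The curve is strictly decreasing in pH.
#'
#' @param seq Peptide string over the 20 standard residues.
#' @param pH pH value(s).
#' @param pka pKa table, see \code{\link{pka_set}}.
#' @return Numeric net charge, vectorised over \code{pH}.
#' @export
net_charge <- function(seq, pH, pka = pka_set()) {
  seq <- check_peptide(seq, allow_x = FALSE)
  ch <- seq_chars(seq)
  basic <- c(Nterm = 1, H = sum(ch == "H"), K = sum(ch == "K"),
             R = sum(ch == "R"))
  acidic <- c(Cterm = 1, C = sum(ch == "C"), D = sum(ch == "D"),
              E = sum(ch == "E"), Y = sum(ch == "Y"))
  vapply(pH, function(p) {
    pos <- sum(vapply(names(basic), function(g) {
      basic[[g]] / (1 + 10^(p - pka[[g]]))
    }, numeric(1)))
    neg <- sum(vapply(names(acidic), function(g) {
      acidic[[g]] / (1 + 10^(pka[[g]] - p))
    }, numeric(1)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point of a peptide
#'
#' Locates the pH at which the net charge vanishes by bisection on
#' [0, 14]. The charge curve is strictly decreasing, so the root is
#' unique; iteration stops when |charge| < \code{tol}.
#'
#' @param seq Peptide string.
#' @param pka pKa table, see \code{\link{pka_set}}.
#' @param tol Charge tolerance at the reported pI.
#' @param max_iter Iteration cap (guards the impossible non-convergent
#'   case).
#' @return The pI as a pH value.
#' @export
isoelectric_point <- function(seq, pka = pka_set(), tol = 1e-6,
                              max_iter = 200L) {
  lo <- 0; hi <- 14
  f_lo <- net_charge(seq, lo, pka)
  f_hi <- net_charge(seq, hi, pka)
  if (f_lo < 0 || f_hi > 0) {
    stop("net charge does not change sign on [0, 14]", call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f <- net_charge(seq, mid, pka)
    if (abs(f) < tol) return(mid)
    if (f > 0) lo <- mid else hi <- mid
  }
  stop("isoelectric point search did not converge", call. = FALSE)
}
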