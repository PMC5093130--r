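# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths.

AA20_T <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(n, alphabet = AA20_T) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- elemental-composition mass oracle -------------------------------
# Residue formulas (C, H, N, O, S) and monoisotopic atomic masses;
# neutral peptide mass = sum(residues) + H2O.
RESIDUE_FORMULA <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))
ATOM_MONO <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069)

oracle_peptide_mass <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  atoms <- Reduce(`+`, RESIDUE_FORMULA[ch])
  atoms <- atoms + c(0, 2, 0, 1, 0)  # water
  sum(atoms * ATOM_MONO[c("C", "H", "N", "O", "S")])
}

# --- regex-based chitin-motif oracle ---------------------------------
# Overlapping matches of the default (wildcard-X, {F,W,Y} aromatics)
# motif via a lookahead regex; independent of the package scanner.
oracle_motif_positions <- function(seq) {
  m <- gregexpr("(?=S.[FWY].[FWY]CG.{4}[FWY])", seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# --- brute-force ORF oracle ------------------------------------------
# Exhaustive ATG->stop scan in all six frames; returns the same column
# layout as find_orfs() (longest ORF per stop; no partials).
oracle_orfs <- function(nt, min_aa) {
  code <- Biostrings::getGeneticCode("1")
  n <- nchar(nt)
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  out <- list()
  for (fr in c(1, 2, 3, -1, -2, -3)) {
    ws <- if (fr > 0) nt else revcomp(nt)
    off <- abs(fr) - 1
    n_codons <- (n - off) %/% 3
    if (n_codons < 1) next
    codons <- substring(ws, off + 3 * (seq_len(n_codons) - 1) + 1,
                        off + 3 * seq_len(n_codons))
    aa <- unname(code[codons])
    claimed_stop <- rep(FALSE, n_codons + 1)
    for (i in seq_len(n_codons)) {
      if (aa[i] != "M") next
      j <- i
      while (j <= n_codons && aa[j] != "*") j <- j + 1
      if (j > n_codons) next        # no stop: partial, skip
      if (claimed_stop[j]) next     # keep only the longest per stop
      claimed_stop[j] <- TRUE
      prot <- paste(aa[i:(j - 1)], collapse = "")
      if (nchar(prot) < min_aa) next
      ws_s <- off + 3 * (i - 1) + 1
      ws_e <- off + 3 * (j - 1)
      if (fr > 0) {
        s <- ws_s; e <- ws_e
      } else {
        s <- n - ws_e + 1; e <- n - ws_s + 1
      }
      out[[length(out) + 1]] <- data.frame(
        frame = fr, nt_start = s, nt_end = e, length_aa = nchar(prot),
        protein = prot, partial = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(frame = integer(), nt_start = integer(),
                      nt_end = integer(), length_aa = integer(),
                      protein = character(), partial = logical()))
  }
  do.call(rbind, out)
}

# --- random additive distance matrices -------------------------------
random_additive_matrix <- function(n_leaves) {
  tr <- ape::unroot(ape::rtree(n_leaves,
                               br = function(k) runif(k, 0.1, 1)))
  ape::cophenetic.phylo(tr)
}

sort_orf_table <- function(x) {
  x <- x[order(x$frame, x$nt_start, x$nt_end), , drop = FALSE]
  rownames(x) <- NULL
  x
}
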