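# Internal helpers shared across modules.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA21 <- c(AA20, "X")
NT5 <- c("A", "C", "G", "T", "N")

# Split a sequence string into a character vector of single residues.
seq_chars <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1]]
}

assert_scalar_string <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  invisible(x)
}

# Validate a peptide sequence over the 20 amino acids (+ optional X);
# returns the uppercased sequence.
check_peptide <- function(seq, allow_x = TRUE, what = "sequence") {
  assert_scalar_string(seq, what)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop(what, " is empty", call. = FALSE)
  ok <- if (allow_x) AA21 else AA20
  bad <- setdiff(unique(seq_chars(seq)), ok)
  if (length(bad) > 0L) {
    stop("invalid residue(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  seq
}

check_nucleotide <- function(seq, what = "sequence") {
  assert_scalar_string(seq, what)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop(what, " is empty", call. = FALSE)
  bad <- setdiff(unique(seq_chars(seq)), NT5)
  if (length(bad) > 0L) {
    stop("invalid nucleotide(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  seq
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

roman_labels <- function(n) as.character(utils::as.roman(seq_len(n)))
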