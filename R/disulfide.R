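# Disulfide connectivity enumeration over abstract cysteine labels
# I..n (mapped to sequence positions via detect_framework()).

parse_label <- function(x, n_cys) {
  if (is.numeric(x)) {
    i <- as.integer(x)
  } else {
    i <- match(toupper(x), roman_labels(n_cys))
  }
  if (is.na(i) || i < 1L || i > n_cys) {
    stop("invalid cysteine label: ", x, call. = FALSE)
  }
  i
}

canonical_bonds <- function(bonds) {
  bonds <- lapply(bonds, function(b) sort(as.integer(b)))
  bonds[order(vapply(bonds, `[`, integer(1), 1L))]
}

pattern_string <- function(bonds, n_cys) {
  lab <- roman_labels(n_cys)
  paste(vapply(bonds, function(b) paste(lab[b], collapse = "-"), ""),
        collapse = ",")
}

new_pattern <- function(bonds, n_cys) {
  bonds <- canonical_bonds(bonds)
  structure(list(bonds = bonds, n_cys = as.integer(n_cys),
                 string = pattern_string(bonds, n_cys)),
            class = "disulfide_pattern")
}

#' @export
print.disulfide_pattern <- function(x, ...) {
  cat(x$string, "\n")
  invisible(x)
}

#' @export
format.disulfide_pattern <- function(x, ...) x$string

# All perfect matchings of the integer set `free`, smallest-first pairing.
match_free <- function(free) {
  if (length(free) == 0L) return(list(list()))
  a <- free[1L]
  out <- list()
  for (b in free[-1L]) {
    rest <- match_free(setdiff(free, c(a, b)))
    for (m in rest) out[[length(out) + 1L]] <- c(list(c(a, b)), m)
  }
  out
}

#' Enumerate disulfide connectivity patterns
#'
#' Lists every way of pairing \code{n_cys} cysteines into disulfide
#' bonds (perfect matchings), optionally constrained to contain fixed
#' bonds known from experiment (e.g. an unambiguous NOE between one Cys
#' pair). With \code{2k} unconstrained cysteines there are
#' \code{(2k-1)!!} patterns: 8 free cysteines give 105; fixing one pair
#' leaves 6 free and 15 patterns. Patterns are returned in canonical
#' form (each bond low-high, bonds sorted by first label) and
#' deterministic lexicographic order.
#'
#' @param n_cys Even number of cysteines.
#' @param fixed List of fixed bonds, each a length-2 vector of labels
#'   (roman numerals like \code{c("II","V")} or integers).
#' @return List of \code{disulfide_pattern} objects.
#' @examples
#' length(enumerate_patterns(8, fixed = list(c("II", "V"))))  # 15
#' @export
enumerate_patterns <- function(n_cys, fixed = list()) {
  n_cys <- as.integer(n_cys)
  if (n_cys < 2L || n_cys %% 2L != 0L) {
    stop("n_cys must be a positive even integer", call. = FALSE)
  }
  fixed_bonds <- lapply(fixed, function(p) {
    if (length(p) != 2L) stop("fixed bonds must be pairs", call. = FALSE)
    b <- sort(c(parse_label(p[[1L]], n_cys), parse_label(p[[2L]], n_cys)))
    if (b[1L] == b[2L]) stop("self-bond in fixed pairs", call. = FALSE)
    b
  })
  used <- unlist(fixed_bonds)
  if (anyDuplicated(used)) {
    stop("conflicting fixed pairs: a cysteine appears twice", call. = FALSE)
  }
  free <- setdiff(seq_len(n_cys), used)
  patterns <- lapply(match_free(free), function(m) {
    new_pattern(c(fixed_bonds, m), n_cys)
  })
  patterns[order(vapply(patterns, `[[`, "", "string"), method = "radix")]
}

#' Rank disulfide patterns by supplied energies
#'
#' Orders candidate connectivity patterns by externally computed
#' structural energies (e.g. from restrained structure calculation),
#' ascending, with ties broken by the canonical pattern order of the
#' input (stable sort). The lowest-energy pattern is the supported
#' connectivity call.
#'
#' @param patterns List of \code{disulfide_pattern}s (e.g. from
#'   \code{\link{enumerate_patterns}}).
#' @param energies Named numeric vector, names matching the patterns'
#'   canonical strings, values in kcal/mol; or a data frame with columns
#'   \code{pattern} and \code{energy}.
#' @return Data frame with columns \code{rank}, \code{pattern},
#'   \code{energy}, ascending in energy.
#' @export
rank_patterns <- function(patterns, energies) {
  if (is.data.frame(energies)) {
    energies <- stats::setNames(energies$energy, energies$pattern)
  }
  strings <- vapply(patterns, `[[`, "", "string")
  missing <- setdiff(strings, names(energies))
  if (length(missing) > 0L) {
    stop("no energy supplied for pattern(s): ",
         paste(missing, collapse = "; "), call. = FALSE)
  }
  e <- unname(energies[strings])
  if (any(!is.finite(e))) {
    stop("non-finite energy for pattern(s): ",
         paste(strings[!is.finite(e)], collapse = "; "), call. = FALSE)
  }
  ord <- order(e, method = "radix")  # stable: ties keep canonical order
  data.frame(rank = seq_along(ord), pattern = strings[ord],
             energy = e[ord], stringsAsFactors = FALSE)
}
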