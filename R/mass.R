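# Standard amino-acid residue masses (Da). Monoisotopic values from the
# usual proteomics reference tables; average masses from the 2021 IUPAC
# standard atomic weights.

RESIDUE_MONO <- c(
  G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048461, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295)

RESIDUE_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

MASS_WATER_MONO <- 18.010565
MASS_WATER_AVG <- 18.0153
MASS_PROTON <- 1.007276
MASS_HYDROGEN <- 1.007825

ALKYL_REAGENTS <- c(carboxymethyl = 58.00548,
                    carbamidomethyl = 57.02146,
                    nominal = 58.0)

#' Define an S-alkylation model
#'
#' Mass added per alkylated cysteine, used to count cysteines from the
#' intact-mass shift between native and reduced/S-alkylated species.
#' Carboxymethylation (iodoacetic acid) adds 58.00548 Da per Cys,
#' carbamidomethylation (iodoacetamide) 57.02146 Da; \code{"nominal"} is
#' the integer 58 Da per Cys used in low-resolution shift arithmetic
#' (8 Cys -> 464 Da). The reference state says what the shift is measured
#' against: \code{"reduced"} (free thiols; shift is n_cys * reagent) or
#' \code{"native"} (disulfide-bonded; each half-cystine also regains one
#' hydrogen, so the per-Cys shift is reagent + 1.007825 Da).
#'
#' @param reagent One of \code{"carboxymethyl"}, \code{"carbamidomethyl"},
#'   \code{"nominal"}.
#' @param reference \code{"reduced"} or \code{"native"}.
#' @return List of class \code{alkylation_model}.
#' @export
alkylation_model <- function(reagent = c("carboxymethyl",
                                         "carbamidomethyl", "nominal"),
                             reference = c("reduced", "native")) {
  reagent <- match.arg(reagent)
  reference <- match.arg(reference)
  structure(list(reagent = reagent,
                 reagent_mass = unname(ALKYL_REAGENTS[reagent]),
                 reference = reference),
            class = "alkylation_model")
}

per_cys_shift <- function(model) {
  model$reagent_mass + if (model$reference == "native") MASS_HYDROGEN else 0
}

#' Peptide mass under disulfide and alkylation states
#'
#' Computes the neutral monoisotopic or average mass of a peptide as the
#' sum of residue masses plus one water, minus two hydrogens per
#' disulfide bond, plus the reagent mass per cysteine if S-alkylated
#' (alkylation applies to the fully reduced species, so it excludes
#' disulfides).
#'
#' @param seq Peptide string over the 20 standard residues
#'   (undetermined \code{X} is an error).
#' @param kind \code{"monoisotopic"} or \code{"average"}.
#' @param n_disulfides Number of disulfide bonds (<= floor(n_cys / 2)).
#' @param alkylation Optional \code{\link{alkylation_model}}; requires
#'   \code{n_disulfides = 0}.
#' @return List of class \code{mass_result}: \code{mass}, \code{kind},
#'   \code{state}, \code{mh_plus} (singly protonated ion mass).
#' @examples
#' peptide_mass(gb5_sequence, n_disulfides = 4)$mass  # 4241.7 Da
#' @export
peptide_mass <- function(seq, kind = c("monoisotopic", "average"),
                         n_disulfides = 0L, alkylation = NULL) {
  kind <- match.arg(kind)
  seq <- check_peptide(seq, allow_x = TRUE)
  ch <- seq_chars(seq)
  tab <- if (kind == "monoisotopic") RESIDUE_MONO else RESIDUE_AVG
  bad <- setdiff(unique(ch), names(tab))
  if (length(bad) > 0L) {
    stop("no mass defined for residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_cys <- sum(ch == "C")
  if (n_disulfides < 0L || n_disulfides > n_cys %/% 2L) {
    stop("n_disulfides must be between 0 and floor(n_cys/2) = ",
         n_cys %/% 2L, call. = FALSE)
  }
  if (!is.null(alkylation) && n_disulfides > 0L) {
    stop("alkylation applies to the reduced species; set n_disulfides = 0",
         call. = FALSE)
  }
  water <- if (kind == "monoisotopic") MASS_WATER_MONO else MASS_WATER_AVG
  mass <- sum(tab[ch]) + water - 2 * n_disulfides * MASS_HYDROGEN
  state <- "reduced"
  if (!is.null(alkylation)) {
    mass <- mass + n_cys * alkylation$reagent_mass
    state <- paste0("alkylated (", alkylation$reagent, ")")
  } else if (n_disulfides > 0L) {
    state <- paste0(n_disulfides, " disulfide",
                    if (n_disulfides > 1L) "s" else "")
  }
  structure(list(mass = mass, kind = kind, state = state,
                 mh_plus = mass + MASS_PROTON),
            class = "mass_result")
}

#' @export
print.mass_result <- function(x, ...) {
  cat(sprintf("%s mass (%s): %.4f Da   [M+H]+ %.4f Da\n",
              x$kind, x$state, x$mass, x$mh_plus))
  invisible(x)
}

#' Singly protonated ion mass
#'
#' @param mass Neutral mass in Da (> 0).
#' @return \code{mass + 1.007276} Da (proton mass, not hydrogen atom).
#' @export
mh_plus <- function(mass) {
  if (!is.numeric(mass) || any(mass <= 0)) {
    stop("mass must be positive", call. = FALSE)
  }
  mass + MASS_PROTON
}

#' Total S-alkylation mass shift
#'
#' @param n_cys Number of cysteines (>= 0).
#' @param model An \code{\link{alkylation_model}}.
#' @return The expected total shift in Da.
#' @examples
#' alkylation_shift(8, alkylation_model("nominal"))  # 464 Da
#' @export
alkylation_shift <- function(n_cys, model = alkylation_model()) {
  if (!is.numeric(n_cys) || n_cys < 0) {
    stop("n_cys must be >= 0", call. = FALSE)
  }
  n_cys * per_cys_shift(model)
}

#' Infer cysteine count from an alkylation mass shift
#'
#' Divides the observed intact-mass shift by the per-cysteine shift of
#' the alkylation model and rounds to the nearest integer. The call is
#' rejected as ambiguous when the residual exceeds
#' \code{tol_frac * per_cys_shift} (default a quarter of one Cys).
#'
#' @param observed_shift Observed mass shift in Da (>= 0).
#' @param model An \code{\link{alkylation_model}}.
#' @param tol_frac Acceptable residual, as a fraction of the per-Cys
#'   shift.
#' @return Integer cysteine count.
#' @examples
#' cys_count_from_shift(464, alkylation_model("nominal"))  # 8
#' @export
cys_count_from_shift <- function(observed_shift,
                                 model = alkylation_model(),
                                 tol_frac = 0.25) {
  if (!is.numeric(observed_shift) || observed_shift < 0) {
    stop("observed_shift must be >= 0", call. = FALSE)
  }
  per <- per_cys_shift(model)
  n <- round(observed_shift / per)
  resid <- abs(observed_shift - n * per)
  if (resid > tol_frac * per) {
    lo <- floor(observed_shift / per)
    stop(sprintf(
      "ambiguous shift %.3f Da: between %d Cys (%.3f Da) and %d Cys (%.3f Da)",
      observed_shift, lo, lo * per, lo + 1, (lo + 1) * per), call. = FALSE)
  }
  as.integer(n)
}
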