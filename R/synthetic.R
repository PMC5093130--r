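# Synthetic hevein-like peptides and precursors with ground truth.
# The generator emits sequences that satisfy their labelled class
# definition by construction: non-anchor positions are drawn from
# residue pools that exclude Cys (and Pro, which is planted explicitly),
# so no accidental frameworks or flanks arise.

AA_FILL <- setdiff(AA20, c("C", "P"))
AA_SMALL <- c("G", "A", "S", "T", "N", "D")
AA_ARO <- c("F", "Y", "W")

#' Generator configuration
#'
#' Study-condition defaults for the synthetic generator: mature domains
#' of 40-50 residues with 3-6 prolines for the Pro-rich class, signal
#' peptides of 20-30 residues cleaved at a Gly|Asp site, and C-terminal
#' tails of 20 residues (cargo-free), 126 (Barwin-like cargo) or 254
#' (class I chitinase cargo).
#'
#' @param mature_len Length-2 range of mature-domain lengths.
#' @param pro_range Length-2 range of Pro counts for Pro-rich peptides.
#' @param signal_len Length-2 range of signal-peptide lengths.
#' @param c_tail_len Named lengths for the three C-tail modes.
#' @param cleavage Cleavage dipeptide (signal last residue, mature
#'   first residue).
#' @return List of class \code{generator_config}.
#' @export
generator_config <- function(mature_len = c(40L, 50L),
                             pro_range = c(3L, 6L),
                             signal_len = c(20L, 30L),
                             c_tail_len = c(short = 20L, barwin = 126L,
                                            chitinase = 254L),
                             cleavage = c("G", "D")) {
  if (mature_len[1L] < 31L) {
    stop("mature_len below the 8C framework minimum (31 residues)",
         call. = FALSE)
  }
  structure(list(mature_len = as.integer(mature_len),
                 pro_range = as.integer(pro_range),
                 signal_len = as.integer(signal_len),
                 c_tail_len = c_tail_len, cleavage = cleavage),
            class = "generator_config")
}

sample_fill <- function(n) sample(AA_FILL, n, replace = TRUE)

# Split `total` into `k` parts, each >= min_part. RNG must be seeded.
split_lengths <- function(total, k, min_part = 2L) {
  extra <- total - k * min_part
  if (extra < 0L) stop("infeasible length split", call. = FALSE)
  parts <- rep(min_part, k)
  if (extra > 0L) {
    add <- table(factor(sample(k, extra, replace = TRUE), levels = 1:k))
    parts <- parts + as.integer(add)
  }
  parts
}

# Core mature-domain builder (RNG must be seeded by the caller).
# Returns list(sequence, truth) with motif/pro ground truth.
build_mature <- function(subfamily, config) {
  target <- sample(config$mature_len[1L]:config$mature_len[2L], 1L)
  pro_flanks <- subfamily == "pro_rich_8C"
  n_term <- if (pro_flanks) c("D", "P", sample_fill(1L)) else {
    c("D", sample_fill(2L))
  }
  loop3 <- c("S", sample_fill(1L), sample(AA_ARO, 1L),
             sample_fill(1L), sample(AA_ARO, 1L))
  loop4 <- c("G", sample(AA_SMALL, 4L, replace = TRUE), "Y")
  tail7 <- if (pro_flanks) "P" else sample_fill(1L)
  fixed_len <- switch(subfamily,
                      pro_rich_8C = 23L, "8C" = 23L,
                      "6C" = 18L, "10C" = 27L)
  if (target < fixed_len + 8L) target <- fixed_len + 8L
  if (subfamily %in% c("pro_rich_8C", "8C")) {
    vl <- split_lengths(target - 23L, 4L)
    L <- lapply(vl, sample_fill)
    parts <- list(n_term, "C", L[[1L]], "C", L[[2L]], "C", "C", loop3,
                  "C", loop4, "C", L[[3L]], "C", L[[4L]], "C", tail7)
    var_idx <- c(3L, 5L, 12L, 14L)
  } else if (subfamily == "6C") {
    # truncated framework C-C-CC-C-C: chitin domain kept, C-tail free
    vl <- split_lengths(target - 18L, 3L)
    L <- lapply(vl, sample_fill)
    parts <- list(n_term, "C", L[[1L]], "C", L[[2L]], "C", "C", loop3,
                  "C", loop4, "C", L[[3L]])
    var_idx <- c(3L, 5L, 12L)
  } else {  # 10C: 8C framework with an extra C-terminal disulfide pair
    vl <- split_lengths(target - 27L, 6L)
    L <- lapply(vl, sample_fill)
    parts <- list(n_term, "C", L[[1L]], "C", L[[2L]], "C", "C", loop3,
                  "C", loop4, "C", L[[3L]], "C", L[[4L]], "C", L[[5L]],
                  "C", L[[6L]], "C", tail7)
    var_idx <- c(3L, 5L, 12L, 14L, 16L, 18L)
  }
  # plant interior prolines into the variable loops
  n_pro_target <- sample(config$pro_range[1L]:config$pro_range[2L], 1L)
  planted <- if (pro_flanks) 2L else 0L
  k_extra <- if (subfamily == "pro_rich_8C") {
    max(0L, n_pro_target - planted)
  } else if (subfamily == "8C") 0L else {
    sample(0L:2L, 1L)
  }
  if (k_extra > 0L) {
    slots <- do.call(rbind, lapply(var_idx, function(i) {
      cbind(i, seq_along(parts[[i]]))
    }))
    pick <- slots[sample(nrow(slots), min(k_extra, nrow(slots))), ,
                  drop = FALSE]
    for (r in seq_len(nrow(pick))) {
      parts[[pick[r, 1L]]][pick[r, 2L]] <- "P"
    }
  }
  seqv <- unlist(parts)
  mature <- paste(seqv, collapse = "")
  ser_abs <- length(n_term) + 1L + length(parts[[3L]]) + 1L +
    length(parts[[5L]]) + 2L + 1L
  list(sequence = mature,
       truth = list(subfamily = subfamily,
                    motif_ser = ser_abs,
                    pro_positions = which(seqv == "P"),
                    length = nchar(mature)))
}

#' Generate a synthetic mature hevein-like peptide
#'
#' Emits a mature peptide that satisfies its labelled subfamily
#' definition exactly: the canonical cysteine framework, a
#' chitin-binding motif planted across loops 3-4, and (for the Pro-rich
#' 8C class) 3-6 prolines with Pro flanking both termini. Reproducible
#' for a fixed seed.
#'
#' @param subfamily One of \code{"pro_rich_8C"}, \code{"8C"},
#'   \code{"6C"}, \code{"10C"}.
#' @param seed Optional integer seed (the caller's RNG state is
#'   restored afterwards).
#' @param config A \code{\link{generator_config}}.
#' @param id,organism Record metadata.
#' @return List with \code{record} (list: \code{id}, \code{sequence},
#'   \code{organism}, \code{description}) and \code{truth} (subfamily,
#'   planted motif Ser position, Pro positions).
#' @export
generate_peptide <- function(subfamily = c("pro_rich_8C", "8C", "6C",
                                           "10C"),
                             seed = NULL, config = generator_config(),
                             id = "synthetic_peptide", organism = "") {
  subfamily <- match.arg(subfamily)
  with_seed(seed, {
    m <- build_mature(subfamily, config)
    list(record = list(id = id, sequence = m$sequence,
                       organism = organism,
                       description = paste("synthetic", subfamily,
                                           "mature peptide")),
         truth = m$truth)
  })
}

# Signal peptide ending in the cleavage residue, free of decoy cleavage
# sites within the partition search window. RNG must be seeded.
build_signal <- function(len, cleavage, window = c(15L, 35L)) {
  sig <- sample_fill(len)
  sig[len] <- cleavage[1L]
  lo <- min(window[1L], len)
  if (len > lo) {
    for (p in lo:(len - 1L)) {
      if (sig[p] == cleavage[1L] && p + 1L <= len &&
          sig[p + 1L] == cleavage[2L]) {
        sig[p] <- "A"
      }
    }
  }
  paste(sig, collapse = "")
}

build_c_tail <- function(mode, config) {
  paste(sample_fill(config$c_tail_len[[mode]]), collapse = "")
}

#' Generate a synthetic precursor with ground-truth boundaries
#'
#' Builds a three-domain precursor: a signal peptide ending at the
#' configured cleavage dipeptide (Gly|Asp by default), a mature
#' hevein-like domain, and a C-terminal tail that is either short and
#' cargo-free (20 aa) or carries a protein-cargo stand-in (126 aa
#' Barwin-like, 254 aa chitinase). The rule-based
#' \code{\link{partition_domains}} recovers the generated boundaries on
#' default-configuration records.
#'
#' @param c_tail_mode \code{"short"}, \code{"barwin"} or
#'   \code{"chitinase"}.
#' @param seed Optional integer seed.
#' @param config A \code{\link{generator_config}}.
#' @param subfamily Mature-domain class, see
#'   \code{\link{generate_peptide}}.
#' @param id,organism Record metadata.
#' @return List with \code{record} (a \code{\link{precursor_record}}
#'   partitioned at the generated ground truth) and \code{truth}
#'   (boundaries, mode, mature-domain truth).
#' @export
generate_precursor <- function(c_tail_mode = c("short", "barwin",
                                               "chitinase"),
                               seed = NULL, config = generator_config(),
                               subfamily = "pro_rich_8C",
                               id = "synthetic_precursor",
                               organism = "") {
  c_tail_mode <- match.arg(c_tail_mode)
  with_seed(seed, {
    build_precursor_seeded(c_tail_mode, config, subfamily, id, organism)
  })
}

build_precursor_seeded <- function(c_tail_mode, config, subfamily, id,
                                   organism,
                                   mature = NULL, signal_len = NULL) {
  if (is.null(mature)) mature <- build_mature(subfamily, config)
  if (is.null(signal_len)) {
    signal_len <- sample(config$signal_len[1L]:config$signal_len[2L], 1L)
  }
  signal <- build_signal(signal_len, config$cleavage)
  c_tail <- build_c_tail(c_tail_mode, config)
  full <- paste0(signal, mature$sequence, c_tail)
  rec <- precursor_record(
    id, full, organism,
    signal_end = signal_len,
    mature_end = signal_len + nchar(mature$sequence),
    cleavage_rule_used = "generator truth")
  list(record = rec,
       truth = list(signal_end = signal_len,
                    mature_end = signal_len + nchar(mature$sequence),
                    c_tail_mode = c_tail_mode,
                    mature = mature$truth))
}

FIXTURE_ORGANISMS <- c(
  "Calocedrus decurrens", "Cunninghamia lanceolata",
  "Cupressus dupreziana", "Platycladus orientalis",
  "Sequoiadendron giganteum", "Taiwania cryptomerioides",
  "Ginkgo biloba", "Pinus sylvestris", "Picea abies", "Abies alba",
  "Taxus baccata", "Podocarpus macrophyllus", "Cephalotaxus harringtonii",
  "Stangeria eriopus", "Juniperus communis", "Thuja plicata",
  "Larix decidua", "Cedrus atlantica", "Tsuga canadensis",
  "Pseudotsuga menziesii", "Araucaria araucana", "Agathis australis",
  "Torreya nucifera", "Amentotaxus argotaenia", "Keteleeria davidiana",
  "Nothotsuga longibracteata", "Cathaya argyrophylla",
  "Sciadopitys verticillata", "Metasequoia glyptostroboides",
  "Glyptostrobus pensilis", "Taxodium distichum", "Cryptomeria japonica",
  "Athrotaxis selaginoides", "Widdringtonia nodiflora",
  "Tetraclinis articulata", "Microbiota decussata", "Fokienia hodginsii",
  "Chamaecyparis obtusa", "Callitris columellaris",
  "Actinostrobus pyramidalis", "Diselma archeri", "Fitzroya cupressoides",
  "Pilgerodendron uviferum", "Austrocedrus chilensis",
  "Libocedrus bidwillii", "Papuacedrus papuana",
  "Neocallitropsis pancheri")

# Replace one non-anchor loop-1 residue of a partitioned record's mature
# domain with `res`. Loop 1 interior is fill-only, so the substitution
# cannot disturb framework, motif or flank criteria.
poison_mature <- function(rec, res) {
  fw <- detect_framework(rec$mature)
  pos_in_mature <- fw$cys_positions[1L] + 1L  # first residue of loop 1
  abs_pos <- rec$signal_end + pos_in_mature
  full <- rec$full_sequence
  substr(full, abs_pos, abs_pos) <- res
  precursor_record(rec$id, full, rec$organism,
                   signal_end = rec$signal_end,
                   mature_end = rec$mature_end,
                   cleavage_rule_used = rec$cleavage_rule_used)
}

#' Deterministic homolog-screen fixture
#'
#' Generates the 85-record precursor set that mirrors the composition
#' of the transcriptome homolog screen: 52 valid Pro-rich 8C precursors
#' whose mature domains collapse to 42 unique sequences (six domains
#' shared across plants with multiplicities 6,2,2,2,2,2), plus five
#' decoy categories each violating exactly one filter criterion --
#' 1 odd-cysteine, 3 short-signal (< 10 aa), 3 with an undetermined
#' \code{X} residue, 9 same-plant full-sequence duplicates, and 17
#' lacking Pro flanks. Organisms are drawn from 47 distinct plant
#' labels; duplicates always follow their originals in record order.
#' Decoy purity is asserted at generation time by running the filter.
#'
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param config A \code{\link{generator_config}}.
#' @return List with \code{records} (list of 85 partitioned
#'   \code{\link{precursor_record}}s) and \code{truth} (data frame:
#'   \code{id}, \code{category}, \code{domain}, \code{organism}).
#' @export
screen_fixture <- function(seed = 1L, config = generator_config()) {
  out <- with_seed(seed, build_fixture(config))
  res <- filter_homologs(out$records)
  counts <- vapply(res$report$removed, `[[`, integer(1), "count")
  expected <- c(odd_cys = 1L, short_signal = 3L, undetermined = 3L,
                duplicate_same_plant = 9L, missing_pro_flanks = 17L)
  if (!identical(counts[names(expected)], expected) ||
      length(res$survivors) != 52L) {
    stop("internal error: fixture decoys are not criterion-pure",
         call. = FALSE)
  }
  out
}

build_fixture <- function(config) {
  orgs <- FIXTURE_ORGANISMS
  # 42 distinct mature domains
  domains <- list()
  seen <- character()
  while (length(domains) < 42L) {
    m <- build_mature("pro_rich_8C", config)
    if (!(m$sequence %in% seen)) {
      seen <- c(seen, m$sequence)
      domains[[length(domains) + 1L]] <- m
    }
  }
  survivors <- list()
  truth <- list()
  add_survivor <- function(domain_idx, organism) {
    i <- length(survivors) + 1L
    id <- sprintf("gh%03d", i)
    pr <- build_precursor_seeded("short", config, "pro_rich_8C", id,
                                 organism, mature = domains[[domain_idx]])
    survivors[[i]] <<- pr$record
    truth[[length(truth) + 1L]] <<- data.frame(
      id = id, category = "none", domain = domain_idx,
      organism = organism, stringsAsFactors = FALSE)
  }
  # shared domains: one in six plants, five in two plants each
  for (o in 1:6) add_survivor(1L, orgs[o])
  oi <- 7L
  for (dom in 2:6) {
    for (k in 1:2) {
      add_survivor(dom, orgs[oi])
      oi <- oi + 1L
    }
  }
  # singleton domains 7..42
  for (dom in 7:42) {
    add_survivor(dom, orgs[((oi - 1L) %% length(orgs)) + 1L])
    oi <- oi + 1L
  }
  decoys <- list()
  dtruth <- list()
  add_decoy <- function(rec, category) {
    decoys[[length(decoys) + 1L]] <<- rec
    dtruth[[length(dtruth) + 1L]] <<- data.frame(
      id = rec$id, category = category, domain = NA_integer_,
      organism = rec$organism, stringsAsFactors = FALSE)
  }
  decoy_org <- function() sample(orgs, 1L)
  # 1 odd-Cys: an extra Cys planted in loop 1 of a valid mature
  pr <- build_precursor_seeded("short", config, "pro_rich_8C",
                               "dx_oddcys_1", decoy_org())
  add_decoy(poison_mature(pr$record, "C"), "odd_cys")
  # 3 short signals (< 10 aa)
  for (k in 1:3) {
    pr <- build_precursor_seeded("short", config, "pro_rich_8C",
                                 sprintf("dx_sigshort_%d", k),
                                 decoy_org(),
                                 signal_len = sample(5:9, 1L))
    add_decoy(pr$record, "short_signal")
  }
  # 3 undetermined: a single X inside the mature domain
  for (k in 1:3) {
    pr <- build_precursor_seeded("short", config, "pro_rich_8C",
                                 sprintf("dx_undet_%d", k), decoy_org())
    add_decoy(poison_mature(pr$record, "X"), "undetermined")
  }
  # 17 missing Pro flanks
  for (k in 1:17) {
    pr <- build_precursor_seeded("short", config, "8C",
                                 sprintf("dx_noflank_%d", k),
                                 decoy_org())
    add_decoy(pr$record, "missing_pro_flanks")
  }
  # interleave the 76 non-duplicates
  base <- c(survivors, decoys)
  btruth <- c(truth, dtruth)
  ord <- sample(length(base))
  base <- base[ord]
  btruth <- btruth[ord]
  # 9 same-plant duplicates of distinct singleton survivors, each
  # inserted after its original
  dup_sources <- sprintf("gh%03d", 17:25)
  ids_now <- vapply(base, `[[`, "", "id")
  for (k in 1:9) {
    src_pos <- match(dup_sources[k], ids_now)
    src <- base[[src_pos]]
    dup <- precursor_record(sprintf("dx_dup_%d", k), src$full_sequence,
                            src$organism, signal_end = src$signal_end,
                            mature_end = src$mature_end,
                            cleavage_rule_used = src$cleavage_rule_used)
    ins <- src_pos + sample.int(length(base) - src_pos + 1L, 1L)
    base <- append(base, list(dup), after = ins - 1L)
    btruth <- append(btruth, list(data.frame(
      id = dup$id, category = "duplicate_same_plant",
      domain = NA_integer_, organism = dup$organism,
      stringsAsFactors = FALSE)), after = ins - 1L)
    ids_now <- vapply(base, `[[`, "", "id")
  }
  list(records = base, truth = do.call(rbind, btruth))
}
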