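#' Criteria for the homolog screen filter
#'
#' The five-criterion manual filter applied to candidate hevein-like
#' precursors from a homology screen, in its canonical order:
#' \enumerate{
#'   \item \code{odd_cys}: odd number of cysteines in the mature domain;
#'   \item \code{short_signal}: signal peptide shorter than
#'     \code{min_signal} residues;
#'   \item \code{undetermined}: undetermined/untranslated residues (any
#'     \code{X} in the full sequence, or an unlocatable mature domain);
#'   \item \code{duplicate_same_plant}: identical full precursor
#'     sequence from the same organism (the first occurrence in input
#'     order is kept);
#'   \item \code{missing_pro_flanks}: mature domain lacking a Pro flank
#'     at either terminus.
#' }
#' Each removed record is attributed to the first criterion it violates.
#'
#' @param order Criterion names in application order.
#' @param min_signal Minimum signal-peptide length.
#' @param n_window,c_window Pro-flank windows on the mature domain.
#' @param strict_signal When \code{TRUE} (default), records with no
#'   derivable signal peptide fail \code{short_signal}.
#' @return List of class \code{filter_criteria}.
#' @export
filter_criteria <- function(order = c("odd_cys", "short_signal",
                                      "undetermined",
                                      "duplicate_same_plant",
                                      "missing_pro_flanks"),
                            min_signal = 10L,
                            n_window = 3L, c_window = 2L,
                            strict_signal = TRUE) {
  known <- c("odd_cys", "short_signal", "undetermined",
             "duplicate_same_plant", "missing_pro_flanks")
  bad <- setdiff(order, known)
  if (length(bad)) {
    stop("unknown criteria: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(order = order, min_signal = as.integer(min_signal),
                 n_window = as.integer(n_window),
                 c_window = as.integer(c_window),
                 strict_signal = strict_signal),
            class = "filter_criteria")
}

violates_criterion <- function(rec, criterion, criteria, seen_keys) {
  switch(criterion,
    odd_cys = {
      if (is.na(rec$mature)) FALSE  # caught by `undetermined`
      else sum(seq_chars(rec$mature) == "C") %% 2L == 1L
    },
    short_signal = {
      if (is.na(rec$signal)) criteria$strict_signal
      else nchar(rec$signal) < criteria$min_signal
    },
    undetermined = {
      grepl("X", rec$full_sequence, fixed = TRUE) || is.na(rec$mature)
    },
    duplicate_same_plant = {
      paste(rec$full_sequence, rec$organism, sep = "\r") %in% seen_keys
    },
    missing_pro_flanks = {
      if (is.na(rec$mature)) FALSE
      else {
        pm <- pro_metrics(rec$mature, criteria$n_window,
                          criteria$c_window)
        !(pm$n_flank && pm$c_flank)
      }
    })
}

#' Apply the five-criterion homolog filter
#'
#' Filters a list of partitioned \code{\link{precursor_record}}s,
#' attributing each removal to the first violated criterion, and returns
#' the survivors with a per-criterion report. The
#' \code{duplicate_same_plant} criterion compares against all records
#' processed earlier in the input, so the first occurrence of an
#' identical same-organism sequence is kept.
#'
#' @param records List of \code{\link{precursor_record}}s.
#' @param criteria A \code{\link{filter_criteria}}.
#' @return List with \code{survivors} (list of records) and
#'   \code{report} (class \code{filter_report}: \code{input_count},
#'   \code{removed} named list of \code{list(count, ids)},
#'   \code{survivor_ids}).
#' @export
filter_homologs <- function(records, criteria = filter_criteria()) {
  if (inherits(records, "precursor_record")) records <- list(records)
  removed <- stats::setNames(
    lapply(criteria$order, function(x) list(count = 0L, ids = character())),
    criteria$order)
  survivors <- list()
  survivor_ids <- character()
  seen_keys <- character()
  for (rec in records) {
    hit <- NA_character_
    for (criterion in criteria$order) {
      if (violates_criterion(rec, criterion, criteria, seen_keys)) {
        hit <- criterion
        break
      }
    }
    seen_keys <- c(seen_keys,
                   paste(rec$full_sequence, rec$organism, sep = "\r"))
    if (is.na(hit)) {
      survivors[[length(survivors) + 1L]] <- rec
      survivor_ids <- c(survivor_ids, rec$id)
    } else {
      removed[[hit]]$count <- removed[[hit]]$count + 1L
      removed[[hit]]$ids <- c(removed[[hit]]$ids, rec$id)
    }
  }
  report <- structure(list(input_count = length(records),
                           removed = removed,
                           survivor_ids = survivor_ids),
                      class = "filter_report")
  list(survivors = survivors, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Homolog filter:", x$input_count, "in,",
      length(x$survivor_ids), "survive\n")
  for (nm in names(x$removed)) {
    cat(sprintf("  removed by %-20s %d\n", paste0(nm, ":"),
                x$removed[[nm]]$count))
  }
  invisible(x)
}

#' Group filter survivors by mature-domain sequence
#'
#' Homologs from different plants can share an identical mature domain
#' while differing in signal peptide and/or C-tail; such records count
#' as one putative peptide. Groups records by exact mature-domain
#' string and reports the unique domains and the multi-plant groups.
#'
#' @param survivors List of \code{\link{precursor_record}}s with mature
#'   domains set.
#' @return List of class \code{mature_groups}: \code{n_unique},
#'   \code{groups} (named list, mature sequence -> data frame of
#'   \code{id}, \code{organism}), \code{multi_plant} (names of groups
#'   spanning more than one organism), \code{n_multi_plant}.
#' @export
unique_mature_domains <- function(survivors) {
  if (inherits(survivors, "precursor_record")) survivors <- list(survivors)
  matures <- vapply(survivors, function(r) r$mature, character(1))
  if (anyNA(matures)) {
    bad <- vapply(survivors[is.na(matures)], function(r) r$id, character(1))
    stop("mature domain unset for record(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ids <- vapply(survivors, function(r) r$id, character(1))
  orgs <- vapply(survivors, function(r) r$organism, character(1))
  idx <- split(seq_along(survivors), factor(matures, levels = unique(matures)))
  groups <- lapply(idx, function(i) {
    data.frame(id = ids[i], organism = orgs[i], stringsAsFactors = FALSE)
  })
  multi <- names(groups)[vapply(groups, function(g) {
    length(unique(g$organism)) > 1L
  }, logical(1))]
  structure(list(n_unique = length(groups), groups = groups,
                 multi_plant = multi, n_multi_plant = length(multi)),
            class = "mature_groups")
}

#' @export
print.mature_groups <- function(x, ...) {
  cat("Unique mature domains:", x$n_unique,
      sprintf("(%d shared across plants)\n", x$n_multi_plant))
  invisible(x)
}
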