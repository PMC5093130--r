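check_alignment <- function(alignment) {
  if (is.data.frame(alignment)) {
    alignment <- stats::setNames(alignment$sequence, alignment$id)
  }
  if (!is.character(alignment) || length(alignment) < 2L) {
    stop("alignment needs at least two sequences", call. = FALSE)
  }
  if (is.null(names(alignment)) || any(names(alignment) == "")) {
    stop("alignment rows must be named", call. = FALSE)
  }
  alignment <- toupper(alignment)
  if (length(unique(nchar(alignment))) != 1L) {
    stop("alignment rows must all have the same length", call. = FALSE)
  }
  alignment
}

#' Pairwise p-distances from an alignment
#'
#' Computes the proportion of mismatched sites for every sequence pair,
#' with pairwise deletion of gap sites by default (a site enters a
#' pair's denominator only when both rows are non-gap). An optional
#' Poisson correction \code{-log(1 - p)} for multiple substitutions is
#' available. p-distances after pairwise deletion need not satisfy the
#' triangle inequality.
#'
#' @param alignment Named character vector of equal-length gapped
#'   sequences (gap \code{"-"}), or a data frame with \code{id} and
#'   \code{sequence} columns.
#' @param correction \code{"none"} or \code{"poisson"}.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
p_distance <- function(alignment, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  alignment <- check_alignment(alignment)
  n <- length(alignment)
  mat <- do.call(rbind, lapply(alignment, seq_chars))
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable sites for pair ", names(alignment)[i], " / ",
             names(alignment)[j], call. = FALSE)
      }
      p <- mean(mat[i, ok] != mat[j, ok])
      if (correction == "poisson") {
        if (p >= 1) {
          stop("Poisson correction undefined at p = 1 for pair ",
               names(alignment)[i], " / ", names(alignment)[j],
               call. = FALSE)
        }
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

# Quote a Newick label if it contains characters outside the safe set.
newick_label <- function(x) {
  if (grepl("[][ \t():;,']", x)) {
    paste0("'", gsub("'", "''", x), "'")
  } else x
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining: agglomerates the pair minimising the
#' Q-criterion, with the usual branch-length and distance-update
#' formulas, until three nodes remain and are joined at an unrooted
#' (trifurcating) root. Ties in Q are broken deterministically by the
#' lexicographically smallest pair of cluster labels (a cluster is
#' labelled by its smallest leaf). Negative branch lengths are clamped
#' to zero with a message. On additive matrices the leaf-to-leaf path
#' lengths of the result reproduce the input exactly.
#'
#' @param d Symmetric distance matrix with dimnames (labels).
#' @return An \code{ape} \code{phylo} tree. For two taxa, a single edge
#'   split into two half-lengths \code{d/2}.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix must have labels",
                            call. = FALSE)
  n <- nrow(d)
  if (n < 2L) stop("need at least two taxa", call. = FALSE)
  clamp <- function(x) {
    if (x < 0) {
      message("negative branch length ", format(x), " clamped to 0")
      0
    } else x
  }
  frag <- function(node, len) {
    sprintf("%s:%.17g", node, clamp(len))
  }
  if (n == 2L) {
    nwk <- sprintf("(%s,%s);",
                   frag(newick_label(labels[1L]), d[1L, 2L] / 2),
                   frag(newick_label(labels[2L]), d[1L, 2L] / 2))
    return(ape::read.tree(text = nwk))
  }
  # active nodes: newick fragments, sort keys (smallest leaf label)
  nodes <- vapply(labels, newick_label, "")
  keys <- labels
  D <- unname(d)
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(D)
    best <- NULL
    best_q <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        take <- FALSE
        if (q < best_q - 1e-12) {
          take <- TRUE
        } else if (abs(q - best_q) <= 1e-12) {
          cand <- sort(c(keys[i], keys[j]))
          cur <- sort(c(keys[best[1L]], keys[best[2L]]))
          if (cand[1L] < cur[1L] ||
              (cand[1L] == cur[1L] && cand[2L] < cur[2L])) take <- TRUE
        }
        if (take) {
          best <- c(i, j)
          best_q <- q
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    new_node <- sprintf("(%s,%s)", frag(nodes[i], bi), frag(nodes[j], bj))
    new_key <- min(keys[i], keys[j])
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nodes <- c(nodes[keep], new_node)
    keys <- c(keys[keep], new_key)
  }
  b1 <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  b2 <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  b3 <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  nwk <- sprintf("(%s,%s,%s);", frag(nodes[1L], b1), frag(nodes[2L], b2),
                 frag(nodes[3L], b3))
  ape::read.tree(text = nwk)
}

#' Write a tree as a Newick string
#'
#' Serialises a \code{phylo} tree to Newick with branch lengths rounded
#' to six decimals; labels containing spaces or Newick metacharacters
#' are single-quoted. Re-parsing (e.g. with \code{ape::read.tree})
#' yields an isomorphic tree.
#'
#' @param tree An \code{ape} \code{phylo} object.
#' @param digits Decimals for branch lengths.
#' @param path Optional file to write to.
#' @return The Newick string (invisibly when \code{path} is given).
#' @export
write_newick <- function(tree, digits = 6L, path = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object",
                                     call. = FALSE)
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  lens <- tree$edge.length
  rec <- function(node, edge_idx) {
    part <- if (node <= n_tip) {
      newick_label(tree$tip.label[node])
    } else {
      kids <- children[[as.character(node)]]
      paste0("(", paste(vapply(kids, function(e) {
        rec(tree$edge[e, 2L], e)
      }, ""), collapse = ","), ")")
    }
    if (!is.null(edge_idx) && !is.null(lens)) {
      part <- sprintf("%s:%.*f", part, digits, lens[edge_idx])
    }
    part
  }
  root <- n_tip + 1L
  nwk <- paste0(rec(root, NULL), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Per-column residue frequencies and information content
#'
#' Computes the position frequency matrix of a protein alignment and
#' each column's information content, the quantities drawn as letter
#' heights in a sequence logo: per column the frequency of each of the
#' 20 residues (gaps and \code{X} excluded from the denominator) and
#' \code{R = log2(20) - H} bits, where \code{H} is the column's Shannon
#' entropy. An optional small-sample correction subtracts
#' \code{(20 - 1) / (2 ln(2) n)} from \code{R} (clamped at zero).
#'
#' @param alignment Named character vector of equal-length gapped rows.
#' @param small_sample_correction Apply the correction (default off).
#' @return List of class \code{profile_matrix}: \code{freq} (20 x L
#'   matrix; \code{NA} columns where all rows are gaps), \code{info}
#'   (length-L numeric, bits), \code{n_nongap} (length-L counts),
#'   \code{all_gap} (logical flags).
#' @export
profile_matrix <- function(alignment, small_sample_correction = FALSE) {
  alignment <- check_alignment(alignment)
  mat <- do.call(rbind, lapply(alignment, seq_chars))
  L <- ncol(mat)
  freq <- matrix(NA_real_, nrow = 20L, ncol = L,
                 dimnames = list(AA20, NULL))
  info <- rep(NA_real_, L)
  n_nongap <- integer(L)
  for (k in seq_len(L)) {
    col <- mat[, k]
    col <- col[col %in% AA20]
    n_nongap[k] <- length(col)
    if (length(col) == 0L) next
    p <- table(factor(col, levels = AA20)) / length(col)
    freq[, k] <- as.numeric(p)
    nz <- p[p > 0]
    h <- -sum(nz * log2(nz))
    r <- log2(20) - h
    if (small_sample_correction) {
      r <- max(0, r - (20 - 1) / (2 * log(2) * length(col)))
    }
    info[k] <- r
  }
  structure(list(freq = freq, info = info, n_nongap = n_nongap,
                 all_gap = n_nongap == 0L),
            class = "profile_matrix")
}

#' Pairwise global alignment (plumbing)
#'
#' A basic Needleman-Wunsch global aligner for unaligned sequence
#' pairs, wrapped over \code{Biostrings::pairwiseAlignment} with a flat
#' match/mismatch score. This is convenience plumbing, not a substitute
#' for a proper multiple aligner: multi-sequence inputs to the distance
#' and logo functions are expected to be pre-aligned.
#'
#' @param a,b Peptide strings.
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return Named character vector of the two aligned (gapped) rows.
#' @export
align_global <- function(a, b, match = 1, mismatch = -1,
                         gap_open = 2, gap_extend = 1) {
  a <- check_peptide(a); b <- check_peptide(b)
  sub <- matrix(mismatch, 21L, 21L, dimnames = list(AA21, AA21))
  diag(sub) <- match
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = sub,
    gapOpening = gap_open, gapExtension = gap_extend)
  c(a = as.character(Biostrings::alignedPattern(aln)),
    b = as.character(Biostrings::alignedSubject(aln)))
}
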