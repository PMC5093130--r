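#' Read a FASTA file
#'
#' Reads protein or nucleotide FASTA into a data frame of records.
#' Sequences are uppercased on read and validated against the module
#' alphabet (20 amino acids plus \code{X} for proteins; \code{ACGTN} for
#' nucleotides). Duplicate ids are suffixed \code{.2}, \code{.3}, ... with
#' a warning; empty records are an error.
#'
#' @param path Path to a FASTA file.
#' @param type \code{"protein"} or \code{"nucleotide"}.
#' @return A data frame with columns \code{id}, \code{sequence},
#'   \code{description} (the header text after the first whitespace).
#' @export
read_fasta <- function(path, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    warning("duplicate ids suffixed: ", paste(dups, collapse = ", "),
            call. = FALSE)
    ids <- make.unique(ids, sep = ".")
  }
  checker <- if (type == "protein") check_peptide else check_nucleotide
  for (i in seq_along(seqs)) checker(seqs[i], what = ids[i])
  data.frame(id = ids, sequence = unname(seqs), description = unname(desc),
             stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records A data frame with columns \code{id} and \code{sequence}
#'   (optionally \code{description}), or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          description = "", stringsAsFactors = FALSE)
  }
  if (is.null(records$description)) records$description <- ""
  headers <- ifelse(nchar(records$description) > 0L,
                    paste(records$id, records$description),
                    records$id)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq Nucleotide string over \code{ACGTN}.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(seq) {
  seq <- check_nucleotide(seq)
  paste(rev(seq_chars(chartr("ACGT", "TGCA", seq))), collapse = "")
}

translate_frame <- function(seq, offset, code) {
  n <- nchar(seq)
  if (n - offset < 3L) return("")
  starts <- seq.int(offset + 1L, by = 3L,
                    length.out = (n - offset) %/% 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames. Frames
#' \code{+1..+3} read the forward strand at offsets 0..2; frames
#' \code{-1..-3} read the reverse complement likewise. Trailing partial
#' codons are dropped, stop codons are rendered \code{*}, and codons
#' containing \code{N} translate to \code{X}.
#'
#' @param seq Nucleotide string (length >= 3).
#' @param table NCBI genetic code table id (default 1, standard).
#' @return Named character vector of six amino-acid strings, names
#'   \code{"+1".."+3","-1".."-3"}.
#' @export
six_frame_translate <- function(seq, table = 1L) {
  seq <- check_nucleotide(seq)
  if (nchar(seq) < 3L) stop("sequence shorter than one codon", call. = FALSE)
  code <- Biostrings::getGeneticCode(as.character(table))
  rc <- paste(rev(seq_chars(chartr("ACGT", "TGCA", seq))), collapse = "")
  out <- c(
    "+1" = translate_frame(seq, 0L, code),
    "+2" = translate_frame(seq, 1L, code),
    "+3" = translate_frame(seq, 2L, code),
    "-1" = translate_frame(rc, 0L, code),
    "-2" = translate_frame(rc, 1L, code),
    "-3" = translate_frame(rc, 2L, code)
  )
  out
}

#' Find open reading frames
#'
#' Scans all six frames for ORFs, defined as the region between a start
#' codon (ATG) and the next in-frame stop codon (TAA, TAG, TGA). By
#' default only the longest ORF per stop (the most 5' ATG) is reported;
#' \code{all_starts = TRUE} reports every internal ATG as well. ORFs that
#' run to the end of the sequence without a stop are reported, flagged
#' \code{partial = TRUE}, only when \code{include_partial = TRUE}.
#'
#' Coordinates are 1-based inclusive on the forward strand and cover the
#' coding region excluding the stop codon; for minus frames the protein
#' is read from the reverse complement of \code{nt_start..nt_end}.
#'
#' @param seq Nucleotide string.
#' @param min_aa Minimum protein length in residues (default 25).
#' @param all_starts Report nested ORFs at internal ATGs.
#' @param include_partial Report stop-less ORFs at the sequence end.
#' @param table Genetic code table id.
#' @return Data frame with columns \code{frame}, \code{nt_start},
#'   \code{nt_end}, \code{length_aa}, \code{protein}, \code{partial}.
#' @export
find_orfs <- function(seq, min_aa = 25L, all_starts = FALSE,
                      include_partial = FALSE, table = 1L) {
  seq <- check_nucleotide(seq)
  if (min_aa < 1L) stop("min_aa must be >= 1", call. = FALSE)
  code <- Biostrings::getGeneticCode(as.character(table))
  n <- nchar(seq)
  rc <- paste(rev(seq_chars(chartr("ACGT", "TGCA", seq))), collapse = "")
  rows <- list()
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    ws <- if (fr > 0L) seq else rc
    offset <- abs(fr) - 1L
    aa <- translate_frame(ws, offset, code)
    if (nchar(aa) == 0L) next
    ch <- seq_chars(aa)
    stops <- which(ch == "*")
    seg_bounds <- c(stops, length(ch) + 1L)  # segment ends (exclusive)
    seg_start <- 1L
    for (send in seg_bounds) {
      if (send > seg_start) {
        ms <- seg_start - 1L + which(ch[seg_start:(send - 1L)] == "M")
        if (length(ms) > 0L && !all_starts) ms <- ms[1L]
        is_partial <- send > length(ch)
        for (m in ms) {
          prot <- substr(aa, m, send - 1L)
          if (nchar(prot) < min_aa) next
          if (is_partial && !include_partial) next
          ws_start <- offset + 3L * (m - 1L) + 1L
          ws_end <- offset + 3L * (send - 1L)
          if (fr > 0L) {
            nt_start <- ws_start; nt_end <- ws_end
          } else {
            nt_start <- n - ws_end + 1L; nt_end <- n - ws_start + 1L
          }
          rows[[length(rows) + 1L]] <- data.frame(
            frame = fr, nt_start = nt_start, nt_end = nt_end,
            length_aa = nchar(prot), protein = prot, partial = is_partial,
            stringsAsFactors = FALSE)
        }
      }
      seg_start <- send + 1L
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(frame = integer(), nt_start = integer(),
                      nt_end = integer(), length_aa = integer(),
                      protein = character(), partial = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
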