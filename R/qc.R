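#' Read preprocessing configuration
#'
#' Thresholds for the four-stage FASTQ filter stack: overall base quality,
#' N-base ambiguity, adapter trimming with a minimum-length rule, and
#' ribosomal RNA removal by exact k-mer membership.
#'
#' @param quality_threshold Phred score counted as "good" (default 20).
#' @param min_good_base_fraction A read is discarded when the fraction of
#'   bases at or above `quality_threshold` falls below this (default 0.5;
#'   the rule is strict: exactly 50 percent good bases is kept).
#' @param max_n_fraction Maximum tolerated fraction of `N` bases (strict
#'   greater-than; default 0.05).
#' @param min_length Minimum read length after adapter trimming
#'   (default 20).
#' @param adapter_sequences Character vector of adapter sequences trimmed
#'   from the 3' end (exact prefix match, minimum overlap
#'   `adapter_min_overlap`).
#' @param adapter_min_overlap Minimum exact adapter overlap (default 8).
#' @param rrna_reference Optional path to an rRNA FASTA; when unset the
#'   rRNA filter is skipped with a warning.
#' @param rrna_kmer k-mer size for rRNA membership testing (default 25).
#' @return A validated list of class `qc_config`.
#' @export
qc_config <- function(quality_threshold = 20L,
                      min_good_base_fraction = 0.5,
                      max_n_fraction = 0.05,
                      min_length = 20L,
                      adapter_sequences = character(0),
                      adapter_min_overlap = 8L,
                      rrna_reference = NULL,
                      rrna_kmer = 25L) {
  stopifnot(quality_threshold >= 0, min_length >= 1L,
            min_good_base_fraction >= 0, min_good_base_fraction <= 1,
            max_n_fraction >= 0, max_n_fraction <= 1,
            adapter_min_overlap >= 1L, rrna_kmer >= 1L)
  structure(list(quality_threshold = quality_threshold,
                 min_good_base_fraction = min_good_base_fraction,
                 max_n_fraction = max_n_fraction,
                 min_length = as.integer(min_length),
                 adapter_sequences = toupper(adapter_sequences),
                 adapter_min_overlap = as.integer(adapter_min_overlap),
                 rrna_reference = rrna_reference,
                 rrna_kmer = as.integer(rrna_kmer)),
            class = "qc_config")
}

#' Low-quality read predicate
#'
#' A read is kept iff at least `min_good_base_fraction` of its bases reach
#' the Phred `quality_threshold`; the discard rule is the strict
#' "proportion of good bases less than the threshold".
#'
#' @param quality Integer vector of Phred scores for one read.
#' @param config A [qc_config()].
#' @return `TRUE` to keep the read.
#' @export
filter_low_quality <- function(quality, config = qc_config()) {
  mean(quality >= config$quality_threshold) >= config$min_good_base_fraction
}

#' Ambiguous-base predicate
#'
#' Keeps a read unless its `N` fraction strictly exceeds `max_n_fraction`.
#'
#' @param sequence Read sequence (uppercase).
#' @param config A [qc_config()].
#' @return `TRUE` to keep the read.
#' @export
filter_ambiguous <- function(sequence, config = qc_config()) {
  n_frac <- lengths(gregexpr("N", sequence, fixed = TRUE)) / nchar(sequence)
  if (!grepl("N", sequence, fixed = TRUE)) n_frac <- 0
  n_frac <= config$max_n_fraction
}

#' Trim 3' adapters and apply the minimum-length rule
#'
#' The longest read suffix that is an exact prefix of any configured
#' adapter, with at least `adapter_min_overlap` matching bases, is
#' removed; the read is then discarded if shorter than `min_length`.
#'
#' @param sequence Read sequence.
#' @param quality Integer Phred vector of the same length.
#' @param config A [qc_config()].
#' @return `NULL` when discarded, else `list(sequence, quality)` after
#'   trimming.
#' @export
trim_adapter_read <- function(sequence, quality, config = qc_config()) {
  len <- nchar(sequence)
  keep_len <- len
  for (ad in config$adapter_sequences) {
    max_ov <- min(len, nchar(ad))
    for (ov in rev(seq_len(max_ov))) {
      if (ov < config$adapter_min_overlap) break
      if (substr(sequence, len - ov + 1L, len) == substr(ad, 1L, ov)) {
        keep_len <- min(keep_len, len - ov)
        break
      }
    }
  }
  if (keep_len < config$min_length) return(NULL)
  list(sequence = substr(sequence, 1L, keep_len),
       quality = quality[seq_len(keep_len)])
}

#' Build an rRNA k-mer membership index
#'
#' Indexes every k-mer of the rRNA reference on both strands.
#'
#' @param rrna_seqs Named character vector of rRNA sequences.
#' @param k k-mer size.
#' @return An environment usable as a constant-time k-mer set.
#' @export
build_rrna_index <- function(rrna_seqs, k = 25L) {
  e <- new.env(hash = TRUE, parent = emptyenv())
  for (s in c(rrna_seqs, revcomp(rrna_seqs))) {
    n <- nchar(s)
    if (n < k) next
    for (km in unique(substring(s, 1:(n - k + 1L), k:n))) {
      assign(km, TRUE, envir = e)
    }
  }
  e
}

#' Ribosomal-RNA read predicate
#'
#' Discards a read when any of its k-mers occurs in the rRNA index
#' (either strand, since the index holds both).
#'
#' @param sequence Read sequence.
#' @param rrna_index Index from [build_rrna_index()], or `NULL` to skip.
#' @param config A [qc_config()].
#' @return `TRUE` to keep the read.
#' @export
filter_rrna <- function(sequence, rrna_index, config = qc_config()) {
  if (is.null(rrna_index)) return(TRUE)
  k <- config$rrna_kmer
  n <- nchar(sequence)
  if (n < k) return(TRUE)
  kmers <- substring(sequence, 1:(n - k + 1L), k:n)
  !any(vapply(kmers, exists, logical(1L), envir = rrna_index,
              inherits = FALSE))
}

#' Run the full preprocessing filter stack over a read set
#'
#' Filters are applied in a fixed order -- quality, ambiguity,
#' adapter/length, rRNA -- and a removed read is charged to the first
#' filter that rejects it.  The report satisfies the accounting identity
#' `input = surviving + sum(removed)`.
#'
#' @param reads Read set in the [read_fastq()] layout.
#' @param config A [qc_config()].
#' @return List with `reads` (survivors, adapters trimmed) and `report`
#'   (`input_reads`, `removed_by_filter`, `surviving_reads`).
#' @export
run_qc <- function(reads, config = qc_config()) {
  rrna_index <- NULL
  if (!is.null(config$rrna_reference)) {
    rrna_index <- build_rrna_index(read_fasta(config$rrna_reference),
                                   config$rrna_kmer)
  } else {
    message("run_qc: no rRNA reference configured; rRNA filter skipped")
  }
  removed <- c(low_quality = 0L, ambiguous = 0L, adapter_length = 0L,
               rrna = 0L)
  keep_id <- character(0); keep_seq <- character(0); keep_q <- list()
  for (i in seq_along(reads$id)) {
    sq <- reads$sequence[i]; ql <- reads$quality[[i]]
    if (!filter_low_quality(ql, config)) {
      removed["low_quality"] <- removed["low_quality"] + 1L; next
    }
    if (!filter_ambiguous(sq, config)) {
      removed["ambiguous"] <- removed["ambiguous"] + 1L; next
    }
    tr <- trim_adapter_read(sq, ql, config)
    if (is.null(tr)) {
      removed["adapter_length"] <- removed["adapter_length"] + 1L; next
    }
    if (!filter_rrna(tr$sequence, rrna_index, config)) {
      removed["rrna"] <- removed["rrna"] + 1L; next
    }
    keep_id <- c(keep_id, reads$id[i])
    keep_seq <- c(keep_seq, tr$sequence)
    keep_q[[length(keep_q) + 1L]] <- tr$quality
  }
  report <- list(input_reads = length(reads$id),
                 removed_by_filter = as.list(removed),
                 surviving_reads = length(keep_id))
  list(reads = list(id = keep_id, sequence = keep_seq, quality = keep_q),
       report = report)
}
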