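#' Back-splice detector configuration
#'
#' @param anchor_length Terminal anchor length in bases (>= 10,
#'   default 20).
#' @param max_span Maximum genomic span of a called circle (default
#'   100000, generous for circles up to ~100 kb).
#' @param min_junction_reads Minimum supporting junction reads for a
#'   reported call (default 2).
#' @param allowed_signals Donor/acceptor dinucleotide pairs accepted as
#'   splice signals on the sense strand (default `"GT-AG"`).
#' @return A validated list of class `detector_config`.
#' @export
detector_config <- function(anchor_length = 20L,
                            max_span = 100000L,
                            min_junction_reads = 2L,
                            allowed_signals = "GT-AG") {
  stopifnot(anchor_length >= 10L, max_span > 0, min_junction_reads >= 1L,
            length(allowed_signals) >= 1L)
  structure(list(anchor_length = as.integer(anchor_length),
                 max_span = as.numeric(max_span),
                 min_junction_reads = as.integer(min_junction_reads),
                 allowed_signals = allowed_signals),
            class = "detector_config")
}

#' Build an exact-match anchor index over the genome
#'
#' Maps every forward-strand k-mer to its genomic location(s).  Queries
#' for the reverse strand are made by the caller with reverse-complemented
#' anchors.  k-mers never span chromosome boundaries.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param anchor_length k-mer size.
#' @return An opaque index object for [detect_backsplice()].
#' @export
build_anchor_index <- function(genome, anchor_length) {
  k <- as.integer(anchor_length)
  if (any(nchar(genome) < k)) {
    stop("anchor length exceeds a chromosome length")
  }
  kmers <- character(0); chrom <- character(0); pos <- integer(0)
  for (ch in names(genome)) {
    n <- nchar(genome[[ch]])
    km <- substring(genome[[ch]], 1:(n - k + 1L), k:n)
    kmers <- c(kmers, km)
    chrom <- c(chrom, rep(ch, length(km)))
    pos <- c(pos, 0:(n - k))                # 0-based start positions
  }
  hits <- split(seq_along(kmers), kmers)
  e <- new.env(hash = TRUE, parent = emptyenv(), size = length(hits))
  list2env(hits, envir = e)
  structure(list(env = e, chrom = chrom, pos = pos, k = k),
            class = "anchor_index")
}

# Look up one anchor; returns data.frame(chrom, pos) of all exact hits.
anchor_hits <- function(index, anchor) {
  idx <- get0(anchor, envir = index$env, inherits = FALSE)
  if (is.null(idx)) {
    return(data.frame(chrom = character(0), pos = integer(0)))
  }
  data.frame(chrom = index$chrom[idx], pos = index$pos[idx],
             stringsAsFactors = FALSE)
}

# Sense-strand splice signal of a candidate circle [s, e) on `strand`.
# Donor follows the circle end in sense direction, acceptor precedes the
# circle start; on "-" these map to reverse-complemented forward flanks.
splice_signal_at <- function(genome, chrom, s, e, strand) {
  n <- nchar(genome[[chrom]])
  if (s < 2L || e + 2L > n) return(NA_character_)
  left <- genome_sub(genome, chrom, s - 2L, s)     # forward flank before start
  right <- genome_sub(genome, chrom, e, e + 2L)    # forward flank after end
  if (strand == "+") paste0(right, "-", left)
  else paste0(revcomp(left), "-", revcomp(right))
}

# One orientation of the anchor test: the read maps forward to the genome,
# candidate breakpoints are scanned for genome contiguity, and the
# breakpoint giving a signal in `allowed` is preferred (leftmost wins).
backsplice_one_orientation <- function(read, index, genome, config, strand) {
  k <- config$anchor_length
  L <- nchar(read)
  a5 <- substr(read, 1L, k)
  a3 <- substr(read, L - k + 1L, L)
  h5 <- anchor_hits(index, a5)
  h3 <- anchor_hits(index, a3)
  if (nrow(h5) == 0L || nrow(h3) == 0L) return(list(status = "unmapped"))
  if (nrow(h5) > 1L || nrow(h3) > 1L) return(list(status = "ambiguous"))
  if (h5$chrom != h3$chrom) return(list(status = "no_candidate"))
  ch <- h5$chrom
  g5 <- h5$pos; g3 <- h3$pos
  if (g3 >= g5) return(list(status = "no_candidate"))  # colinear or overlapping
  span <- g5 - g3 + L - k                              # independent of breakpoint
  if (span > config$max_span) return(list(status = "no_candidate"))
  best <- NULL
  for (b in k:(L - k)) {
    s <- g3 - (L - k - b)                              # circle start
    e <- g5 + b                                        # circle end (exclusive)
    if (s < 0L || e > nchar(genome[[ch]])) next
    if (genome_sub(genome, ch, g5, e) != substr(read, 1L, b)) next
    if (genome_sub(genome, ch, s, s + (L - b)) != substr(read, b + 1L, L)) next
    sig <- splice_signal_at(genome, ch, s, e, strand)
    cand <- list(status = "candidate", chrom = ch, start = s, end = e,
                 strand = strand, splice_signal = sig)
    if (!is.na(sig) && sig %in% config$allowed_signals) {
      return(cand)                                     # leftmost allowed wins
    }
    if (is.null(best)) best <- cand
  }
  if (!is.null(best)) return(best)
  list(status = "no_candidate")
}

#' Detect a back-splice junction in a single read
#'
#' The first and last `anchor_length` bases are mapped exactly; a
#' candidate circle exists when both anchors map uniquely to one
#' chromosome in reversed genomic order within `max_span`.  The breakpoint
#' is then fixed by requiring the whole read to be genome-contiguous on
#' both sides, preferring (leftmost) breakpoints whose flanks spell an
#' allowed splice signal on the sense strand.  Both read orientations are
#' tried; reported coordinates are always on the forward reference with
#' the strand recorded.
#'
#' @param read Read sequence (uppercase A/C/G/T).
#' @param index Index from [build_anchor_index()].
#' @param genome Named character vector of chromosome sequences.
#' @param config A [detector_config()].
#' @return A list with `status` (`candidate`, `no_candidate`, `ambiguous`,
#'   `unmapped`, `too_short`) and, for candidates, `chrom`, `start`,
#'   `end`, `strand`, `splice_signal`.
#' @export
detect_backsplice <- function(read, index, genome, config = detector_config()) {
  if (nchar(read) < 2L * config$anchor_length) return(list(status = "too_short"))
  allowed <- function(x) {
    x$status == "candidate" && !is.na(x$splice_signal) &&
      x$splice_signal %in% config$allowed_signals
  }
  fwd <- backsplice_one_orientation(read, index, genome, config, "+")
  if (allowed(fwd)) return(fwd)
  rev <- backsplice_one_orientation(revcomp(read), index, genome, config, "-")
  if (allowed(rev)) return(rev)
  if (fwd$status == "candidate") return(fwd)
  if (rev$status == "candidate") return(rev)
  if ("ambiguous" %in% c(fwd$status, rev$status)) return(list(status = "ambiguous"))
  list(status = "no_candidate")
}

#' Call circRNAs from one or more read sets
#'
#' Per-read candidates are aggregated by (chrom, start, end, strand); a
#' call is reported when its supporting-read count reaches
#' `min_junction_reads` and its splice signal is allowed.  Output order is
#' deterministic (chrom, start, end).
#'
#' @param reads A single read set ([read_fastq()] layout) or a named list
#'   of read sets, one per sample.
#' @param index Index from [build_anchor_index()].
#' @param genome Named character vector of chromosome sequences.
#' @param config A [detector_config()].
#' @return List with `calls` (data frame: `circ_id`, `chrom`, `start`,
#'   `end`, `strand`, `junction_reads`, `splice_signal`), `sample_counts`
#'   (call x sample matrix of supporting reads), `read_ids` (per-call list
#'   of supporting read ids) and `skipped` (per-status read tallies).
#' @export
call_circrnas <- function(reads, index, genome, config = detector_config()) {
  if (!is.null(reads$sequence)) reads <- list(sample_1 = reads)
  keys <- character(0)
  cand <- list()
  skipped <- c(too_short = 0L, unmapped = 0L, ambiguous = 0L,
               no_candidate = 0L)
  support <- list()   # key -> named per-sample counts
  read_ids <- list()  # key -> supporting read ids
  for (sm in names(reads)) {
    rs <- reads[[sm]]
    for (i in seq_along(rs$sequence)) {
      res <- detect_backsplice(rs$sequence[i], index, genome, config)
      if (res$status != "candidate") {
        skipped[res$status] <- skipped[res$status] + 1L
        next
      }
      key <- paste(res$chrom, res$start, res$end, res$strand, sep = "|")
      if (is.null(cand[[key]])) {
        cand[[key]] <- res
        support[[key]] <- stats::setNames(rep(0L, length(reads)), names(reads))
        read_ids[[key]] <- character(0)
      }
      support[[key]][sm] <- support[[key]][sm] + 1L
      read_ids[[key]] <- c(read_ids[[key]], rs$id[i])
    }
  }
  keys <- names(cand)
  if (!length(keys)) {
    empty <- data.frame(circ_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), junction_reads = integer(0),
                        splice_signal = character(0))
    return(list(calls = empty,
                sample_counts = matrix(0L, 0L, length(reads),
                                       dimnames = list(NULL, names(reads))),
                read_ids = list(), skipped = skipped))
  }
  df <- do.call(rbind, lapply(keys, function(k) {
    x <- cand[[k]]
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               strand = x$strand,
               junction_reads = sum(support[[k]]),
               splice_signal = x$splice_signal, stringsAsFactors = FALSE)
  }))
  keep <- df$junction_reads >= config$min_junction_reads &
    df$splice_signal %in% config$allowed_signals
  df <- df[keep, , drop = FALSE]
  keys <- keys[keep]
  ord <- order(df$chrom, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  keys <- keys[ord]
  df$circ_id <- sprintf("circ_%03d", seq_len(nrow(df)))
  rownames(df) <- NULL
  sc <- do.call(rbind, lapply(keys, function(k) support[[k]]))
  if (is.null(sc)) sc <- matrix(0L, 0L, length(reads))
  dimnames(sc) <- list(df$circ_id, names(reads))
  list(calls = df[, c("circ_id", "chrom", "start", "end", "strand",
                      "junction_reads", "splice_signal")],
       sample_counts = sc,
       read_ids = stats::setNames(read_ids[keys], df$circ_id),
       skipped = skipped)
}

#' Export circRNA calls as BED6 plus a sidecar TSV
#'
#' The BED score column carries the supporting-read count; splice signal
#' and per-sample counts go to the sidecar.
#'
#' @param result Result of [call_circrnas()].
#' @param bed_path,tsv_path Output paths.
#' @return `bed_path`, invisibly.
#' @export
write_circ_calls <- function(result, bed_path, tsv_path) {
  calls <- result$calls
  write_bed(data.frame(chrom = calls$chrom, start = calls$start,
                       end = calls$end, strand = calls$strand,
                       name = calls$circ_id, score = calls$junction_reads),
            bed_path)
  side <- data.frame(calls, result$sample_counts, check.names = FALSE)
  write_tsv(side, tsv_path)
  invisible(bed_path)
}
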