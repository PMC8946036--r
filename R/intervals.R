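#' Create a genomic interval table
#'
#' All coordinates inside the package are 0-based half-open (BED-like):
#' `start` is the 0-based position of the first base, `end` is one past the
#' last base, so `end - start` is the length.  Format readers and writers
#' convert at the boundary; nothing else does.
#'
#' @param chrom Chromosome names (character).
#' @param start 0-based inclusive start positions.
#' @param end Exclusive end positions; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."` per interval.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(is.character(chrom), length(chrom) >= 1L)
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(df$chrom))) stop("chromosome names must be non-empty")
  if (any(df$start < 0) || any(df$start >= df$end)) {
    stop("intervals require 0 <= start < end")
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  df
}

#' Convert an interval table to a GRanges object
#'
#' @param intervals A `data.frame` as produced by [genomic_interval()].
#' @return A [GenomicRanges::GRanges] with 1-based closed ranges.
#' @export
intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end),
    strand = ifelse(intervals$strand == ".", "*", intervals$strand)
  )
}

interval_length <- function(intervals) intervals$end - intervals$start

#' Validate a gene model
#'
#' A gene model is a list with `gene_id`, `chrom`, `strand` and an `exons`
#' interval table.  Exons must be non-overlapping, sorted by start, and all
#' on the gene's chromosome and strand.
#'
#' @param model A gene model list.
#' @return The model, invisibly, after validation.
#' @export
validate_gene_model <- function(model) {
  stopifnot(is.list(model), !is.null(model$gene_id), !is.null(model$exons))
  ex <- model$exons
  if (nrow(ex) == 0L) stop("gene ", model$gene_id, " has no exons")
  if (any(ex$chrom != model$chrom)) {
    stop("gene ", model$gene_id, ": exon on wrong chromosome")
  }
  if (is.unsorted(ex$start)) stop("gene ", model$gene_id, ": exons unsorted")
  if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
    stop("gene ", model$gene_id, ": overlapping exons")
  }
  invisible(model)
}
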