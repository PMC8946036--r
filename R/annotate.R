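#' Classify one circRNA against gene models
#'
#' Categories follow the standard five-way scheme, evaluated on the
#' genomic span of the call.  Among genes on the call's strand
#' ("sense" genes) overlapping the span: span within one exon gives
#' `EciRNA`; span entirely inside one intron gives `IciRNA`; any other
#' sense overlap (mixed exonic/intronic or partially outside the gene)
#' gives `EIciRNA`.  With no sense overlap, an opposite-strand gene
#' overlap gives `antisense`; otherwise `intergenic`.  When several sense
#' genes overlap, the gene with the largest overlap wins, ties going to
#' the smaller gene start.
#'
#' @param call One-row data frame (or list) with `chrom`, `start`, `end`,
#'   `strand` in 0-based half-open coordinates.
#' @param models Named list of gene models.
#' @return List with `category`, `parent_gene` (set for the three
#'   gene-derived categories) and `exon_count` (annotated exons of the
#'   parent gene fully or partly inside the span; 0 otherwise).
#' @export
classify_circ <- function(call, models) {
  s <- call$start; e <- call$end
  on_chrom <- Filter(function(m) m$chrom == call$chrom, models)
  ov_len <- vapply(on_chrom, function(m) {
    max(0, min(e, m$end) - max(s, m$start))
  }, numeric(1L))
  touching <- on_chrom[ov_len > 0]
  ov_len <- ov_len[ov_len > 0]
  sense <- vapply(touching, function(m) m$strand == call$strand, logical(1L))
  if (!any(sense)) {
    if (length(touching)) {
      return(list(category = "antisense", parent_gene = NA_character_,
                  exon_count = 0L))
    }
    return(list(category = "intergenic", parent_gene = NA_character_,
                exon_count = 0L))
  }
  sg <- touching[sense]
  sl <- ov_len[sense]
  starts <- vapply(sg, `[[`, numeric(1L), "start")
  pick <- order(-sl, starts)[1L]
  m <- sg[[pick]]
  ex <- m$exons
  exon_count <- sum(ex$start < e & ex$end > s)
  in_one_exon <- any(ex$start <= s & ex$end >= e)
  category <- if (in_one_exon) {
    "EciRNA"
  } else {
    introns_ok <- FALSE
    if (nrow(ex) > 1L) {
      is_ <- ex$end[-nrow(ex)]; ie_ <- ex$start[-1L]
      introns_ok <- any(is_ <= s & ie_ >= e)
    }
    if (introns_ok) "IciRNA" else "EIciRNA"
  }
  list(category = category, parent_gene = m$gene_id, exon_count = exon_count)
}

#' GC fraction of a sequence
#'
#' `(#G + #C) / (#non-N bases)`; `NA` for an all-N sequence.
#'
#' @param sequence Uppercase A/C/G/T/N string.
#' @return Proportion in `[0, 1]`, or `NA`.
#' @export
gc_fraction <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAString(sequence))
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0) return(NA_real_)
  unname((counts["G"] + counts["C"]) / denom)
}

#' Annotate circRNA calls
#'
#' Adds category, parent gene, exon count, length and GC fraction (from
#' the genomic span sequence on the call strand) to each call.
#'
#' @param calls Call table from [call_circrnas()] (or a truth table with
#'   the same coordinate columns).
#' @param models Named list of gene models.
#' @param genome Named character vector of chromosome sequences; when
#'   supplied, GC content is computed.
#' @return Data frame of per-circRNA annotations.
#' @export
annotate_circs <- function(calls, models, genome = NULL) {
  known <- unique(vapply(models, `[[`, character(1L), "chrom"))
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    if (!call$chrom %in% known) {
      warning("chromosome ", call$chrom, " absent from annotation; ",
              "classifying call ", call$circ_id, " as intergenic")
      cl <- list(category = "intergenic", parent_gene = NA_character_,
                 exon_count = 0L)
    } else {
      cl <- classify_circ(call, models)
    }
    gc <- NA_real_
    if (!is.null(genome)) {
      seq <- genome_sub(genome, call$chrom, call$start, call$end)
      if (call$strand == "-") seq <- revcomp(seq)
      gc <- gc_fraction(seq)
    }
    data.frame(circ_id = call$circ_id, chrom = call$chrom,
               start = call$start, end = call$end, strand = call$strand,
               category = cl$category, parent_gene = cl$parent_gene,
               exon_count = cl$exon_count,
               length = call$end - call$start, gc_fraction = gc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Characterization summary of an annotated circRNA set
#'
#' Computes the standard descriptive panels: per-chromosome counts, a
#' length histogram (200-bp bins up to 2000, then `>2000`), an exon-count
#' histogram, a GC histogram (10-point bins from 30 to 80 percent with
#' open-ended tails), category percentages, a splice-signal tally and the
#' mean length.
#'
#' @param annotations Data frame from [annotate_circs()].
#' @param calls Optional call table supplying `splice_signal`.
#' @return List of summary tables; totals conserve the number of inputs.
#' @export
summarize_circs <- function(annotations, calls = NULL) {
  n <- nrow(annotations)
  if (n == 0L) {
    return(list(n_circ = 0L, per_chromosome = table(character(0)),
                length_hist = table(character(0)),
                exon_hist = table(integer(0)), gc_hist = table(character(0)),
                category_percent = numeric(0), splice_signal = table(character(0)),
                mean_length = NA_real_))
  }
  len_breaks <- c(0, seq(200, 2000, by = 200), Inf)
  len_labels <- c("<=200", paste0(seq(201, 1801, by = 200), "-",
                                  seq(400, 2000, by = 200)), ">2000")
  length_hist <- table(cut(annotations$length, breaks = len_breaks,
                           labels = len_labels, include.lowest = TRUE))
  gc_breaks <- c(-Inf, seq(0.3, 0.8, by = 0.1), Inf)
  gc_labels <- c("<30", "30-40", "40-50", "50-60", "60-70", "70-80", ">80")
  gc <- annotations$gc_fraction
  gc_hist <- table(cut(gc[!is.na(gc)], breaks = gc_breaks, labels = gc_labels,
                       right = TRUE))
  cat_pct <- 100 * table(annotations$category) / n
  list(
    n_circ = n,
    per_chromosome = table(annotations$chrom),
    length_hist = length_hist,
    exon_hist = table(annotations$exon_count),
    gc_hist = gc_hist,
    category_percent = cat_pct,
    splice_signal = if (!is.null(calls)) table(calls$splice_signal)
                    else table(character(0)),
    mean_length = mean(annotations$length)
  )
}
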