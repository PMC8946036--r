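#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; duplicate record names are rejected.
#'
#' @param path Path to a FASTA file (gzip transparent).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  names(seqs) <- nm
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' GFF3 coordinates are 1-based inclusive; they are converted to the
#' package-internal 0-based half-open convention here and nowhere else.
#' Features of type `gene` become models; `exon` features are attached to
#' their `Parent` gene.  A gene without exons, an exon without a parent
#' gene, or an end before a start is a format error.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of gene models (see [validate_gene_model()]).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (any(GenomicRanges::width(gr) < 1L)) stop("GFF3 feature with end < start")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  exons <- gr[type == "exon"]
  gene_ids <- as.character(genes$ID)
  if (anyDuplicated(gene_ids)) stop("duplicate gene IDs in GFF3")
  parents <- vapply(exons$Parent, function(p) {
    if (length(p) != 1L) stop("exon without a single parent gene")
    as.character(p)
  }, character(1L))
  if (!all(parents %in% gene_ids)) {
    stop("exon parent(s) not defined as gene: ",
         paste(unique(setdiff(parents, gene_ids)), collapse = ", "))
  }
  models <- lapply(seq_along(genes), function(i) {
    gid <- gene_ids[i]
    ex <- exons[parents == gid]
    if (length(ex) == 0L) stop("gene ", gid, " has no exons")
    ex <- GenomicRanges::sort(ex)
    model <- list(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(genes[i])),
      strand = as.character(GenomicRanges::strand(genes[i])),
      start = GenomicRanges::start(genes[i]) - 1L,
      end = GenomicRanges::end(genes[i]),
      exons = genomic_interval(
        chrom = as.character(GenomicRanges::seqnames(ex)),
        start = GenomicRanges::start(ex) - 1L,
        end = GenomicRanges::end(ex),
        strand = as.character(GenomicRanges::strand(ex))
      )
    )
    validate_gene_model(model)
    model
  })
  names(models) <- gene_ids
  models
}

#' Write gene models to GFF3
#'
#' @param models Named list of gene models.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  rows <- lapply(models, function(m) {
    n_ex <- nrow(m$exons)
    data.frame(
      chrom = m$chrom,
      start = c(m$start, m$exons$start) + 1L,
      end = c(m$end, m$exons$end),
      strand = m$strand,
      type = c("gene", rep("exon", n_ex)),
      ID = c(m$gene_id, rep(NA_character_, n_ex)),
      Parent = c(NA_character_, rep(m$gene_id, n_ex)),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, unname(rows))
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = df$type, ID = df$ID, Parent = df$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to a FASTQ file.
#' @return A list with `id`, `sequence` (uppercase character vector) and
#'   `quality` (list of integer Phred score vectors).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record near line ", length(lines))
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(list(id = character(0), sequence = character(0), quality = list()))
  }
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad)) stop("malformed FASTQ header at line ", (bad[1L] - 1L) * 4L + 1L)
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad)) {
    stop("sequence/quality length mismatch at line ", (bad[1L] - 1L) * 4L + 2L)
  }
  list(
    id = sub("\\s.*$", "", substring(hd, 2L)),
    sequence = sq,
    quality = lapply(ql, function(q) utf8ToInt(q) - 33L)
  )
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads A read set as returned by [read_fastq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(length(reads$sequence) == length(reads$id),
            length(reads$quality) == length(reads$id))
  qual <- vapply(reads$quality, function(q) intToUtf8(q + 33L), character(1L))
  out <- character(4L * length(reads$id))
  out[seq(1L, by = 4L, length.out = length(reads$id))] <- paste0("@", reads$id)
  out[seq(2L, by = 4L, length.out = length(reads$id))] <- reads$sequence
  out[seq(3L, by = 4L, length.out = length(reads$id))] <- "+"
  out[seq(4L, by = 4L, length.out = length(reads$id))] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' BED is 0-based half-open, matching the internal convention, so the
#' coordinates pass through unchanged.
#'
#' @param intervals Interval table with additional `name` and `score`
#'   columns (missing ones default to `"."` / `0`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  name <- if (!is.null(intervals$name)) intervals$name else "."
  score <- if (!is.null(intervals$score)) intervals$score else 0L
  df <- data.frame(intervals$chrom, sprintf("%d", as.integer(intervals$start)),
                   sprintf("%d", as.integer(intervals$end)),
                   name, score, intervals$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data frame as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with a header row
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an igraph network as GraphML
#'
#' @param graph An [igraph::igraph] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

# Reverse complement of plain character sequences (A/C/G/T/N/U, any case).
revcomp <- function(x) {
  vapply(x, function(s) {
    rawToChar(rev(charToRaw(chartr("ACGTUNacgtun", "TGCAANtgcaan", s))))
  }, character(1L), USE.NAMES = !is.null(names(x)))
}
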