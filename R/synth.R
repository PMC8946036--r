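#' Configuration for the synthetic circRNA study generator
#'
#' Defines every knob of the simulated study: genome geometry, gene models,
#' how many circRNAs of each category are planted, the read simulator, the
#' negative binomial count model and the planted miRNA response elements.
#' Defaults describe a desk-scale study: a three-chromosome genome, fifty
#' planted circRNAs covering all five categories, two groups of three
#' samples, and NB counts at dispersion 0.1.  The circRNA length range
#' defaults to 48-5000 bp (the lower bound matches the shortest circles
#' observed in cattle mammary tissue; the upper bound keeps simulations
#' small -- raise it to explore circles up to ~100 kb).
#'
#' @param seed Integer random seed; every generator operation derives its
#'   stream from it, so an identical config reproduces identical output.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bases.
#' @param n_genes Total number of genes, spread round-robin over
#'   chromosomes with alternating strands.
#' @param exons_per_gene Integer range `c(lo, hi)` of exons per gene.
#' @param exon_length_range,intron_length_range,intergenic_gap_range
#'   Base-pair ranges for gene geometry.
#' @param n_circ_per_category Named integer vector giving the number of
#'   planted circRNAs per category (`EciRNA`, `IciRNA`, `EIciRNA`,
#'   `antisense`, `intergenic`).
#' @param circ_length_range Planted circRNA genomic span range in bases.
#' @param n_samples_per_group Samples per group (groups are
#'   `early_lactation` and `non_lactation`).
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha mu^2);
#'   0 gives Poisson counts.
#' @param de_fraction Fraction of circRNAs planted as differentially
#'   expressed (half up, half down).
#' @param de_log2fc True absolute log2 fold change of planted DE circles
#'   (early_lactation relative to non_lactation).
#' @param base_mean_range Range of per-circRNA baseline means; sampled
#'   log-uniformly.
#' @param library_size_range Range of per-sample depth factors.
#' @param n_mirnas Number of simulated mature miRNAs (22 nt, distinct
#'   2-8 seed regions).
#' @param n_mrnas Number of simulated mRNA (3'UTR-like) sequences.
#' @param n_mre_circles Number of circRNAs given dedicated binding-site
#'   sequences for the ceRNA stage.
#' @param mre_multiplicity_range Range of planted seed-site counts per
#'   selected (RNA, miRNA) pair.
#' @param mre_pair_prob Probability that a given (RNA, miRNA) pair receives
#'   planted sites.
#' @param mre_rna_length Length of the binding-site sequences.
#' @param read_length Simulated read length in bases (junction reads from
#'   circles shorter than this are shortened to the circle length so a
#'   single back-splice breakpoint spans the read).
#' @param junction_reads_per_circ Range of junction-spanning reads emitted
#'   per circle per sample.
#' @param n_background_reads Colinear genome-fragment reads per sample.
#' @param anchor_length Terminal anchor length used when positioning the
#'   breakpoint inside junction reads; must match the detector's anchor.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 3L,
                             chrom_length = 120000L,
                             n_genes = 12L,
                             exons_per_gene = c(2L, 4L),
                             exon_length_range = c(400L, 2000L),
                             intron_length_range = c(800L, 6000L),
                             intergenic_gap_range = c(2000L, 5000L),
                             n_circ_per_category = c(EciRNA = 10L, IciRNA = 10L,
                                                     EIciRNA = 10L, antisense = 10L,
                                                     intergenic = 10L),
                             circ_length_range = c(48L, 5000L),
                             n_samples_per_group = 3L,
                             nb_dispersion = 0.1,
                             de_fraction = 0.2,
                             de_log2fc = 2,
                             base_mean_range = c(20, 500),
                             library_size_range = c(0.7, 1.3),
                             n_mirnas = 12L,
                             n_mrnas = 8L,
                             n_mre_circles = 10L,
                             mre_multiplicity_range = c(1L, 3L),
                             mre_pair_prob = 0.35,
                             mre_rna_length = 300L,
                             read_length = 100L,
                             junction_reads_per_circ = c(3L, 6L),
                             n_background_reads = 100L,
                             anchor_length = 20L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length_range = as.integer(exon_length_range),
              intron_length_range = as.integer(intron_length_range),
              intergenic_gap_range = as.integer(intergenic_gap_range),
              n_circ_per_category = n_circ_per_category,
              circ_length_range = as.integer(circ_length_range),
              n_samples_per_group = as.integer(n_samples_per_group),
              nb_dispersion = nb_dispersion, de_fraction = de_fraction,
              de_log2fc = de_log2fc, base_mean_range = base_mean_range,
              library_size_range = library_size_range,
              n_mirnas = as.integer(n_mirnas), n_mrnas = as.integer(n_mrnas),
              n_mre_circles = as.integer(n_mre_circles),
              mre_multiplicity_range = as.integer(mre_multiplicity_range),
              mre_pair_prob = mre_pair_prob,
              mre_rna_length = as.integer(mre_rna_length),
              read_length = as.integer(read_length),
              junction_reads_per_circ = as.integer(junction_reads_per_circ),
              n_background_reads = as.integer(n_background_reads),
              anchor_length = as.integer(anchor_length))
  counts <- c(cfg$n_chromosomes, cfg$chrom_length, cfg$n_genes,
              cfg$exons_per_gene, cfg$n_samples_per_group, cfg$n_mirnas,
              cfg$read_length)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  if (any(unlist(cfg$n_circ_per_category) < 0L)) {
    stop("circle counts per category must be >= 0")
  }
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    stop("de_fraction must be in [0, 1]")
  }
  if (cfg$circ_length_range[1] < 1L ||
      cfg$circ_length_range[2] > cfg$chrom_length) {
    stop("circ_length_range must lie within chromosome length")
  }
  if (cfg$circ_length_range[1] < 2L * cfg$anchor_length + 8L) {
    # shortest circle must still accommodate a junction read with two anchors
    if (cfg$circ_length_range[1] < 2L * cfg$anchor_length) {
      stop("minimum circle length must be >= 2 * anchor_length")
    }
  }
  if (cfg$read_length < 2L * cfg$anchor_length) {
    stop("read_length must be >= 2 * anchor_length")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate the synthetic reference genome and gene models
#'
#' Chromosomes are i.i.d. random DNA; genes are laid out left to right
#' with random exon/intron geometry, assigned round-robin to chromosomes
#' with alternating strands so both strands are represented.
#'
#' @param config A [synthetic_config()].
#' @return A list with `genome` (named character vector) and `models`
#'   (named list of gene models).
#' @export
generate_genome <- function(config) {
  with_seed(config$seed + 101L, {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    genome <- vapply(chroms, function(ch) random_dna(config$chrom_length),
                     character(1L))
    cursors <- stats::setNames(rep(0L, length(chroms)), chroms)
    models <- vector("list", config$n_genes)
    for (g in seq_len(config$n_genes)) {
      ch <- chroms[((g - 1L) %% length(chroms)) + 1L]
      strand <- if (g %% 2L == 1L) "+" else "-"
      n_ex <- runif_int(1L, config$exons_per_gene[1], config$exons_per_gene[2])
      ex_len <- runif_int(n_ex, config$exon_length_range[1],
                          config$exon_length_range[2])
      in_len <- if (n_ex > 1L) {
        runif_int(n_ex - 1L, config$intron_length_range[1],
                  config$intron_length_range[2])
      } else integer(0)
      gap <- runif_int(1L, config$intergenic_gap_range[1],
                       config$intergenic_gap_range[2])
      start <- cursors[ch] + gap
      glen <- sum(ex_len) + sum(in_len)
      if (start + glen + config$intergenic_gap_range[1] > config$chrom_length) {
        stop("chromosome ", ch, " too short for requested gene models; ",
             "increase chrom_length or reduce n_genes")
      }
      ex_start <- start + c(0L, cumsum(ex_len[-n_ex] + in_len))
      models[[g]] <- list(
        gene_id = sprintf("gene_%02d", g), chrom = ch, strand = strand,
        start = start, end = start + glen,
        exons = genomic_interval(ch, ex_start, ex_start + ex_len, strand)
      )
      cursors[ch] <- start + glen
    }
    names(models) <- vapply(models, `[[`, character(1L), "gene_id")
    lapply(models, validate_gene_model)
    list(genome = genome, models = models)
  })
}

# Replace genome[chrom][pos..pos+nchar(what)-1] (0-based pos) with `what`.
edit_genome <- function(genome, chrom, pos, what) {
  substr(genome[[chrom]], pos + 1L, pos + nchar(what)) <- what
  genome
}

genome_sub <- function(genome, chrom, start, end) {
  # 0-based half-open extraction
  substr(genome[[chrom]], start + 1L, end)
}

#' Plant circRNAs of all five categories into the genome
#'
#' For each category the requested number of back-splice spans is placed at
#' coordinates satisfying that category's definition, mutually disjoint
#' (including 2-bp splice flanks).  Canonical GT-AG donor/acceptor
#' dinucleotides are written into the reference on the circle's sense
#' strand: on `+` circles the forward strand reads `AG` immediately before
#' the span and `GT` immediately after; on `-` circles the forward strand
#' shows the reverse complements `AC` / `CT`.
#'
#' @param config A [synthetic_config()].
#' @param genome Named character vector from [generate_genome()].
#' @param models Gene models from [generate_genome()].
#' @return A list with `circles` (truth table: `circ_id`, `chrom`, `start`,
#'   `end`, `strand`, `category`, `splice_signal`, `length`) and `genome`
#'   (the edited reference).
#' @export
plant_circles <- function(config, genome, models) {
  with_seed(config$seed + 202L, {
    occupied <- list()  # per-chrom matrix of (start, end) incl. flanks
    for (ch in names(genome)) occupied[[ch]] <- matrix(numeric(0), ncol = 2)
    is_free <- function(ch, s, e) {
      occ <- occupied[[ch]]
      !any(occ[, 1] < e & occ[, 2] > s)
    }
    reserve <- function(ch, s, e) {
      occupied[[ch]] <<- rbind(occupied[[ch]], c(s, e))
    }
    lo <- config$circ_length_range[1]; hi <- config$circ_length_range[2]
    rows <- list()
    place_one <- function(category) {
      for (try in seq_len(2000L)) {
        cand <- switch(category,
          EciRNA = {
            m <- models[[sample(length(models), 1L)]]
            ok <- which(interval_length(m$exons) >= lo + 8L)
            if (!length(ok)) next
            ex <- m$exons[sample(rep(ok, 2L), 1L), ]
            len <- runif_int(1L, lo, min(hi, ex$end - ex$start - 4L))
            s <- runif_int(1L, ex$start + 2L, ex$end - len - 2L)
            list(chrom = m$chrom, s = s, e = s + len, strand = m$strand)
          },
          IciRNA = {
            m <- models[[sample(length(models), 1L)]]
            if (nrow(m$exons) < 2L) next
            i <- sample(rep(seq_len(nrow(m$exons) - 1L), 2L), 1L)
            is <- m$exons$end[i]; ie <- m$exons$start[i + 1L]
            if (ie - is < lo + 8L) next
            len <- runif_int(1L, lo, min(hi, ie - is - 6L))
            s <- runif_int(1L, is + 3L, ie - len - 3L)
            list(chrom = m$chrom, s = s, e = s + len, strand = m$strand)
          },
          EIciRNA = {
            m <- models[[sample(length(models), 1L)]]
            if (nrow(m$exons) < 2L) next
            i <- sample(rep(seq_len(nrow(m$exons) - 1L), 2L), 1L)
            b <- m$exons$end[i]                       # exon/intron boundary
            ex_room <- b - m$exons$start[i] - 4L
            in_room <- m$exons$start[i + 1L] - b - 4L
            if (ex_room < 24L || in_room < 24L) next
            d1 <- runif_int(1L, 24L, min(ex_room, hi - 24L))
            d2 <- runif_int(1L, max(24L, lo - d1),
                            min(in_room, hi - d1))
            if (d1 + d2 < lo) next
            list(chrom = m$chrom, s = b - d1, e = b + d2, strand = m$strand)
          },
          antisense = {
            m <- models[[sample(length(models), 1L)]]
            glen <- m$end - m$start
            if (glen < lo + 8L) next
            len <- runif_int(1L, lo, min(hi, glen - 4L))
            s <- runif_int(1L, m$start + 2L, m$end - len - 2L)
            list(chrom = m$chrom, s = s, e = s + len,
                 strand = if (m$strand == "+") "-" else "+")
          },
          intergenic = {
            ch <- names(genome)[sample(length(genome), 1L)]
            gaps <- intergenic_gaps(models, ch, config$chrom_length)
            gaps <- gaps[gaps$end - gaps$start >= lo + 20L, , drop = FALSE]
            if (!nrow(gaps)) next
            gp <- gaps[sample(rep(seq_len(nrow(gaps)), 2L), 1L), ]
            len <- runif_int(1L, lo, min(hi, gp$end - gp$start - 16L))
            s <- runif_int(1L, gp$start + 8L, gp$end - len - 8L)
            list(chrom = ch, s = s, e = s + len,
                 strand = sample(c("+", "-"), 1L))
          },
          stop("unknown category: ", category)
        )
        if (cand$s < 2L || cand$e + 2L > config$chrom_length) next
        if (!is_free(cand$chrom, cand$s - 6L, cand$e + 6L)) next
        reserve(cand$chrom, cand$s - 6L, cand$e + 6L)
        return(cand)
      }
      stop("could not place a circRNA of category '", category,
           "' under the current genome geometry")
    }
    cats <- names(config$n_circ_per_category)
    for (cat in cats) {
      for (j in seq_len(config$n_circ_per_category[[cat]])) {
        cand <- place_one(cat)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cand$chrom, start = cand$s, end = cand$e,
          strand = cand$strand, category = cat, stringsAsFactors = FALSE)
      }
    }
    circles <- do.call(rbind, rows)
    ord <- order(circles$chrom, circles$start, circles$end)
    circles <- circles[ord, , drop = FALSE]
    circles$circ_id <- sprintf("circ_%03d", seq_len(nrow(circles)))
    circles$splice_signal <- "GT-AG"
    circles$length <- circles$end - circles$start
    rownames(circles) <- NULL
    # write sense-strand GT-AG flanks into the reference
    for (i in seq_len(nrow(circles))) {
      ch <- circles$chrom[i]; s <- circles$start[i]; e <- circles$end[i]
      if (circles$strand[i] == "+") {
        genome <- edit_genome(genome, ch, s - 2L, "AG")
        genome <- edit_genome(genome, ch, e, "GT")
      } else {
        genome <- edit_genome(genome, ch, s - 2L, "AC")
        genome <- edit_genome(genome, ch, e, "CT")
      }
    }
    circles <- circles[, c("circ_id", "chrom", "start", "end", "strand",
                           "category", "splice_signal", "length")]
    list(circles = circles, genome = genome)
  })
}

# Gaps on one chromosome not covered by any gene (either strand).
intergenic_gaps <- function(models, chrom, chrom_length) {
  g <- Filter(function(m) m$chrom == chrom, models)
  if (!length(g)) {
    return(data.frame(start = 0L, end = chrom_length))
  }
  s <- vapply(g, `[[`, numeric(1L), "start")
  e <- vapply(g, `[[`, numeric(1L), "end")
  o <- order(s)
  s <- s[o]; e <- e[o]
  gaps <- data.frame(start = c(0, e), end = c(s, chrom_length))
  gaps[gaps$end > gaps$start, , drop = FALSE]
}

# Sense-strand circular sequence of one planted circle.
circle_sequence <- function(genome, circle) {
  seq <- genome_sub(genome, circle$chrom, circle$start, circle$end)
  if (circle$strand == "-") seq <- revcomp(seq)
  seq
}

#' Simulate junction-spanning and background reads
#'
#' Each planted circle emits, per sample, a configured number of
#' junction-spanning reads: the read is the tail of the circular sequence
#' concatenated to its head, with the back-splice breakpoint placed
#' uniformly at least one anchor length from either read end.  Background
#' reads are colinear genome fragments on random strands.  All qualities
#' are Phred 40 (`I`).
#'
#' @param config A [synthetic_config()].
#' @param circles Truth table from [plant_circles()].
#' @param genome Edited genome from [plant_circles()].
#' @return Named list (one element per sample) of read sets in the
#'   [read_fastq()] layout; junction read ids carry the source circle id.
#' @export
simulate_reads <- function(config, circles, genome) {
  k <- config$anchor_length
  if (config$read_length < 2L * k) {
    stop("read_length must be >= 2 * anchor_length")
  }
  with_seed(config$seed + 303L, {
    samples <- sample_sheet(config)$sample_id
    out <- lapply(samples, function(sm) {
      ids <- character(0); seqs <- character(0)
      for (i in seq_len(nrow(circles))) {
        circ <- circles[i, ]
        cs <- circle_sequence(genome, circ)
        clen <- nchar(cs)
        leff <- min(config$read_length, clen)
        n <- runif_int(1L, config$junction_reads_per_circ[1],
                       config$junction_reads_per_circ[2])
        for (j in seq_len(n)) {
          b <- runif_int(1L, k, leff - k)        # bases taken from the tail
          rd <- paste0(substr(cs, clen - b + 1L, clen),
                       substr(cs, 1L, leff - b))
          ids <- c(ids, sprintf("junc|%s|%s|%d", circ$circ_id, sm, j))
          seqs <- c(seqs, rd)
        }
      }
      for (j in seq_len(config$n_background_reads)) {
        ch <- names(genome)[sample(length(genome), 1L)]
        pos <- runif_int(1L, 0L, config$chrom_length - config$read_length)
        frag <- genome_sub(genome, ch, pos, pos + config$read_length)
        if (stats::runif(1) < 0.5) frag <- revcomp(frag)
        ids <- c(ids, sprintf("bg|%s|%d", sm, j))
        seqs <- c(seqs, frag)
      }
      list(id = ids, sequence = seqs,
           quality = lapply(nchar(seqs), function(n) rep(40L, n)))
    })
    names(out) <- samples
    out
  })
}

#' Sample sheet for the two-group design
#'
#' @param config A [synthetic_config()].
#' @return Data frame with `sample_id` and `group` columns; groups are
#'   `early_lactation` and `non_lactation`.
#' @export
sample_sheet <- function(config) {
  n <- config$n_samples_per_group
  data.frame(
    sample_id = c(sprintf("early_%d", seq_len(n)),
                  sprintf("non_%d", seq_len(n))),
    group = rep(c("early_lactation", "non_lactation"), each = n),
    stringsAsFactors = FALSE
  )
}

#' Simulate a negative binomial junction-count matrix
#'
#' Counts are drawn NB(mu, alpha) with per-circle baseline means sampled
#' log-uniformly, per-sample depth factors, and an `early_lactation` group
#' mean scaled by `2^log2fc` for planted DE circles.  `nb_dispersion = 0`
#' gives Poisson draws.
#'
#' @param config A [synthetic_config()].
#' @param circles Truth table from [plant_circles()] (only ids are used).
#' @return List with `counts` (circRNA x sample integer matrix), `samples`
#'   (sample sheet), `size_factors` (true per-sample depth factors) and
#'   `de_labels` (truth: `circ_id`, `true_log2fc`, `label`).
#' @export
simulate_counts <- function(config, circles) {
  if (config$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  with_seed(config$seed + 404L, {
    sheet <- sample_sheet(config)
    n_circ <- nrow(circles)
    mu0 <- exp(stats::runif(n_circ, log(config$base_mean_range[1]),
                            log(config$base_mean_range[2])))
    sf <- stats::runif(nrow(sheet), config$library_size_range[1],
                       config$library_size_range[2])
    n_de <- round(config$de_fraction * n_circ)
    de_idx <- if (n_de > 0) sample(n_circ, n_de) else integer(0)
    lfc <- numeric(n_circ)
    if (n_de > 0) {
      signs <- rep(c(1, -1), length.out = n_de)
      lfc[de_idx] <- signs * config$de_log2fc
    }
    counts <- matrix(0L, n_circ, nrow(sheet),
                     dimnames = list(circles$circ_id, sheet$sample_id))
    for (j in seq_len(nrow(sheet))) {
      mu <- mu0 * sf[j]
      if (sheet$group[j] == "early_lactation") mu <- mu * 2^lfc
      counts[, j] <- if (config$nb_dispersion > 0) {
        stats::rnbinom(n_circ, mu = mu, size = 1 / config$nb_dispersion)
      } else {
        stats::rpois(n_circ, mu)
      }
    }
    label <- ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "null"))
    list(counts = counts, samples = sheet,
         size_factors = stats::setNames(sf, sheet$sample_id),
         de_labels = data.frame(circ_id = circles$circ_id,
                                true_log2fc = lfc, label = label,
                                stringsAsFactors = FALSE))
  })
}

#' Generate mature miRNA sequences with distinct seed regions
#'
#' @param config A [synthetic_config()].
#' @return Named character vector of 22-nt miRNA sequences (DNA alphabet)
#'   whose position 2-8 seeds are pairwise distinct.
#' @export
generate_mirnas <- function(config) {
  with_seed(config$seed + 505L, {
    n <- config$n_mirnas
    for (try in seq_len(200L)) {
      seqs <- vapply(seq_len(n), function(i) random_dna(22L), character(1L))
      if (!anyDuplicated(substr(seqs, 2L, 8L))) {
        names(seqs) <- sprintf("miR_%02d", seq_len(n))
        return(seqs)
      }
    }
    stop("could not generate miRNAs with distinct seeds")
  })
}

#' Plant miRNA seed-complement sites into RNA sequences
#'
#' For each selected (RNA, miRNA) pair the configured number of
#' non-overlapping exact seed-complement 7-mers is embedded in a fresh
#' random backbone sequence.  Each sequence is rejection-sampled until it
#' contains no accidental seed complement for *any* miRNA in the set, so
#' the truth table is exact: downstream seed matching must report exactly
#' the planted multiplicities.
#'
#' @param config A [synthetic_config()].
#' @param circ_ids,mrna_ids RNA identifiers to generate sequences for.
#' @param mirnas Named miRNA sequences from [generate_mirnas()].
#' @return List with `sequences` (named vector over both RNA classes),
#'   `rna_class` (named `circRNA`/`mRNA` vector) and `truth` (data frame
#'   `rna_id`, `rna_class`, `mirna_id`, `site_count`, `site_positions`
#'   with 1-based comma-separated positions).
#' @export
plant_mres <- function(config, circ_ids, mrna_ids, mirnas) {
  seeds <- substr(mirnas, 2L, 8L)
  if (anyDuplicated(seeds)) {
    stop("miRNA set contains duplicated seed regions: ",
         paste(names(mirnas)[duplicated(seeds)], collapse = ", "))
  }
  sites <- revcomp(seeds)        # what a binding site looks like on the RNA
  names(sites) <- names(mirnas)
  rna_ids <- c(circ_ids, mrna_ids)
  rna_class <- stats::setNames(
    rep(c("circRNA", "mRNA"), c(length(circ_ids), length(mrna_ids))), rna_ids)
  with_seed(config$seed + 606L, {
    truth <- list(); seqs <- character(0)
    for (rid in rna_ids) {
      pick <- names(mirnas)[stats::runif(length(mirnas)) < config$mre_pair_prob]
      mult <- stats::setNames(
        runif_int(length(pick), config$mre_multiplicity_range[1],
                  config$mre_multiplicity_range[2]), pick)
      planted <- plant_sites_into_sequence(config$mre_rna_length, sites, mult)
      seqs[rid] <- planted$sequence
      if (length(pick)) {
        truth[[rid]] <- data.frame(
          rna_id = rid, rna_class = rna_class[[rid]], mirna_id = pick,
          site_count = as.integer(mult),
          site_positions = vapply(pick, function(m) {
            paste(planted$positions[[m]], collapse = ",")
          }, character(1L)),
          stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(rna_id = character(0), rna_class = character(0),
                 mirna_id = character(0), site_count = integer(0),
                 site_positions = character(0))
    rownames(truth) <- NULL
    list(sequences = seqs, rna_class = rna_class, truth = truth)
  })
}

# Build one RNA sequence of length `len` containing exactly `mult[m]`
# non-overlapping copies of site 7-mer `sites[m]` and no accidental
# occurrence of any site in `sites`.  Rejection-sampled.
plant_sites_into_sequence <- function(len, sites, mult) {
  total_sites <- sum(mult)
  site_w <- if (length(sites)) nchar(sites[[1]]) else 7L
  if (total_sites * (site_w + 2L) > len) {
    stop("sequence of length ", len, " too short for ", total_sites,
         " planted sites")
  }
  planted_ids <- rep(names(mult), mult)
  for (try in seq_len(1000L)) {
    blocks <- total_sites + 1L
    spacer_len <- len - total_sites * site_w
    lens <- as.integer(stats::rmultinom(1L, spacer_len, rep(1, blocks)))
    order_ids <- if (total_sites) sample(planted_ids) else character(0)
    pieces <- character(2L * total_sites + 1L)
    pos <- integer(total_sites); at <- 0L
    for (b in seq_len(total_sites)) {
      pieces[2L * b - 1L] <- random_dna(lens[b])
      at <- at + lens[b]
      pos[b] <- at + 1L                     # 1-based site start
      pieces[2L * b] <- sites[[order_ids[b]]]
      at <- at + site_w
    }
    pieces[2L * total_sites + 1L] <- random_dna(lens[blocks])
    seq <- paste(pieces, collapse = "")
    # verify: every site's occurrences are exactly the planted ones
    ok <- TRUE
    positions <- stats::setNames(vector("list", length(sites)), names(sites))
    for (m in names(sites)) {
      hits <- all_occurrences(seq, sites[[m]])
      want <- sort(pos[order_ids == m])
      if (!identical(hits, want)) { ok <- FALSE; break }
      positions[[m]] <- want
    }
    if (ok) return(list(sequence = seq, positions = positions))
  }
  stop("rejection sampling failed to produce a contamination-free sequence; ",
       "reduce sequence length, site multiplicity or miRNA count")
}

# All (possibly overlapping) 1-based occurrence positions of `pat` in `x`.
all_occurrences <- function(x, pat) {
  out <- integer(0); from <- 1L
  repeat {
    h <- regexpr(pat, substr(x, from, nchar(x)), fixed = TRUE)
    if (h == -1L) break
    out <- c(out, from + as.integer(h) - 1L)
    from <- from + as.integer(h)          # advance one base: overlaps allowed
  }
  out
}

#' Generate a complete synthetic study
#'
#' Runs every generator stage under the configured seed and, optionally,
#' writes all artifacts to disk: genome FASTA, gene GFF3, per-sample
#' FASTQ, counts and sample-sheet TSVs, miRNA/binding-sequence FASTAs and
#' machine-readable truth tables.
#'
#' @param config A [synthetic_config()].
#' @param outdir Optional output directory (created if missing).
#' @return List with `config`, `genome`, `models`, `circles`, `reads`,
#'   `counts`, `mirnas` and `mre` (see the individual generators).
#' @export
synthesize_study <- function(config = synthetic_config(), outdir = NULL) {
  gen <- generate_genome(config)
  pl <- plant_circles(config, gen$genome, gen$models)
  reads <- simulate_reads(config, pl$circles, pl$genome)
  cnt <- simulate_counts(config, pl$circles)
  mirnas <- generate_mirnas(config)
  with_seed(config$seed + 707L, {
    mre_circ <- sample(pl$circles$circ_id,
                       min(config$n_mre_circles, nrow(pl$circles)))
  })
  mre <- plant_mres(config, sort(mre_circ),
                    sprintf("mRNA_%02d", seq_len(config$n_mrnas)), mirnas)
  study <- list(config = config, genome = pl$genome, models = gen$models,
                circles = pl$circles, reads = reads, counts = cnt,
                mirnas = mirnas, mre = mre)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(study$genome, file.path(outdir, "genome.fa"))
    write_gff3(study$models, file.path(outdir, "genes.gff3"))
    for (sm in names(study$reads)) {
      write_fastq(study$reads[[sm]], file.path(outdir, paste0(sm, ".fastq")))
    }
    cm <- data.frame(circ_id = rownames(cnt$counts), cnt$counts,
                     check.names = FALSE)
    write_tsv(cm, file.path(outdir, "counts.tsv"))
    write_tsv(cnt$samples, file.path(outdir, "samples.tsv"))
    write_tsv(study$circles, file.path(outdir, "truth_circles.tsv"))
    write_tsv(cnt$de_labels, file.path(outdir, "truth_de.tsv"))
    write_tsv(mre$truth, file.path(outdir, "truth_mres.tsv"))
    write_fasta(study$mirnas, file.path(outdir, "mirnas.fa"))
    write_fasta(mre$sequences[mre$rna_class == "circRNA"],
                file.path(outdir, "circ_mre.fa"))
    write_fasta(mre$sequences[mre$rna_class == "mRNA"],
                file.path(outdir, "mrna.fa"))
  }
  study
}
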