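# Shared fixtures, built once per test run.

# Default synthetic study plus its detection result, cached across tests.
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthesize_study(synthetic_config())
    cache
  }
})

default_detection <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      study <- default_study()
      index <- build_anchor_index(study$genome, 20L)
      cache <<- call_circrnas(study$reads, index, study$genome,
                              detector_config())
    }
    cache
  }
})

coord_key <- function(df) paste(df$chrom, df$start, df$end, df$strand)

# A tiny two-gene annotation for classification unit tests:
# gene_plus on chr1 '+' with exons [100,400) and [900,1300);
# gene_minus on chr1 '-' with one exon [5000,6000).
toy_models <- function() {
  list(
    gene_plus = list(
      gene_id = "gene_plus", chrom = "chr1", strand = "+",
      start = 100, end = 1300,
      exons = genomic_interval("chr1", c(100, 900), c(400, 1300), "+")),
    gene_minus = list(
      gene_id = "gene_minus", chrom = "chr1", strand = "-",
      start = 5000, end = 6000,
      exons = genomic_interval("chr1", 5000, 6000, "-"))
  )
}

toy_call <- function(start, end, strand = "+", chrom = "chr1") {
  list(circ_id = "c1", chrom = chrom, start = start, end = end,
       strand = strand)
}

# Independent hypergeometric upper tail by direct binomial-coefficient
# arithmetic (no log-space, no shared code with the implementation).
hyper_tail_oracle <- function(M_T, m_p, m_n, m_c) {
  if (m_c == 0) return(1)
  i <- m_c:min(m_p, m_n)
  sum(choose(m_n, i) * choose(M_T - m_n, m_p - i)) / choose(M_T, m_p)
}

# Independent naive enumeration of the two-group NB conditional exact
# test: explicit loop over all splits of K, summing outcomes no more
# likely than the observed one (same moment-matched group-sum laws).
nb_exact_oracle <- function(kA, kB, sA, sB, dispersion,
                            ssqA = sA^2, ssqB = sB^2) {
  K <- kA + kB
  if (K == 0) return(1)
  q <- K / (sA + sB)
  prob_one <- function(a) {
    if (dispersion > 0) {
      dnbinom(a, mu = sA * q, size = sA^2 / (dispersion * ssqA)) *
        dnbinom(K - a, mu = sB * q, size = sB^2 / (dispersion * ssqB))
    } else {
      dpois(a, sA * q) * dpois(K - a, sB * q)
    }
  }
  joint <- vapply(0:K, prob_one, numeric(1))
  p_obs <- joint[kA + 1]
  sum(joint[joint <= p_obs * (1 + 1e-7)]) / sum(joint)
}

# Six-read QC fixture: each of four filters trips exactly once, two
# reads survive.  Adapter is "AGATCGGAAGAGC"; rRNA reference is a fixed
# 60-mer.
qc_fixture <- function() {
  rrna <- paste(rep(c("ACGGT", "TTGCA"), 6), collapse = "")
  good1 <- strrep("ACGT", 15)
  good2 <- strrep("TGCA", 15)
  adapter <- "AGATCGGAAGAGC"
  reads <- list(
    id = c("lowq", "many_n", "adapter_short", "rrna_copy", "ok1", "ok2"),
    sequence = c(
      good1,                                        # fails quality
      paste0(strrep("N", 6), substr(good1, 7, 60)), # 10% N
      paste0(substr(good1, 1, 12), adapter),        # trims to 12 < 20
      substr(rrna, 1, 60),                          # rRNA k-mer hit
      good1, good2),
    quality = list(
      rep(c(10L, 40L), c(35L, 25L)),  # 25/60 good bases < 50%
      rep(40L, 60L), rep(40L, 25L), rep(40L, 60L),
      rep(40L, 60L), rep(40L, 60L))
  )
  list(reads = reads, rrna = c(rRNA_1 = rrna), adapter = adapter)
}
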