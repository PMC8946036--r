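test_that("genome generation matches the requested geometry", {
  cfg <- synthetic_config(seed = 7, n_chromosomes = 2L, n_genes = 6L,
                          chrom_length = 80000L)
  gen <- generate_genome(cfg)
  expect_length(gen$genome, 2L)
  expect_true(all(nchar(gen$genome) == 80000L))
  expect_length(gen$models, 6L)
  n_ex <- vapply(gen$models, function(m) nrow(m$exons), integer(1L))
  expect_true(all(n_ex >= cfg$exons_per_gene[1] & n_ex <= cfg$exons_per_gene[2]))
  expect_setequal(unique(vapply(gen$models, `[[`, character(1L), "strand")),
                  c("+", "-"))
  # exons non-overlapping and in order
  for (m in gen$models) expect_silent(validate_gene_model(m))
})

test_that("generation is deterministic under a fixed seed, on disk too", {
  cfg <- synthetic_config(seed = 42, n_genes = 4L, chrom_length = 60000L,
                          n_circ_per_category = c(EciRNA = 2L, IciRNA = 2L,
                                                  EIciRNA = 2L, antisense = 2L,
                                                  intergenic = 2L),
                          n_background_reads = 10L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  synthesize_study(cfg, d1)
  synthesize_study(cfg, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("an infeasible gene layout names the problem", {
  cfg <- synthetic_config(chrom_length = 10000L, n_genes = 10L)
  expect_error(generate_genome(cfg), "too short")
})

test_that("planted circles satisfy their category definitions by re-derivation", {
  study <- default_study()
  ann <- annotate_circs(study$circles, study$models)
  expect_identical(ann$category, study$circles$category)
  expect_true(all(study$circles$length >= 48L))
  expect_true(all(study$circles$length <= 5000L))
})

test_that("planted splice flanks read GT-AG on the sense strand", {
  study <- default_study()
  for (i in seq_len(nrow(study$circles))) {
    circ <- study$circles[i, ]
    sig <- circlact:::splice_signal_at(study$genome, circ$chrom, circ$start,
                                       circ$end, circ$strand)
    expect_identical(sig, "GT-AG")
  }
})

test_that("junction read counts and structure follow the configuration", {
  cfg <- synthetic_config(seed = 9, junction_reads_per_circ = c(2L, 2L),
                          n_background_reads = 0L, n_samples_per_group = 1L,
                          n_circ_per_category = c(EciRNA = 3L, IciRNA = 2L))
  study <- synthesize_study(cfg)
  rs <- study$reads[[1]]
  expect_length(rs$id, 2L * nrow(study$circles))
  # first and second read halves map to circle end and circle start
  rd <- rs$sequence[1]
  circ <- study$circles[study$circles$circ_id ==
                          strsplit(rs$id[1], "|", fixed = TRUE)[[1]][2], ]
  cs <- circlact:::circle_sequence(study$genome, circ)
  expect_true(endsWith(paste0(cs, cs), rd) ||
                grepl(rd, paste0(cs, cs), fixed = TRUE))
})

test_that("simulated counts honour the NB moment structure", {
  cfg <- synthetic_config(seed = 3, de_fraction = 0,
                          base_mean_range = c(100, 100),
                          library_size_range = c(1, 1), nb_dispersion = 0.1)
  circles <- data.frame(circ_id = sprintf("c%05d", 1:10000))
  sim <- simulate_counts(cfg, circles)
  x <- as.vector(sim$counts[, 1])
  mu <- mean(x); v <- var(x)
  expect_equal(mu, 100, tolerance = 0.02)
  # variance = mu + alpha mu^2 (= 1100 at mu = 100), within 3 SEs
  se_v <- sqrt((mean((x - mu)^4) - v^2) / length(x))
  expect_lt(abs(v - (mu + 0.1 * mu^2)), 3 * se_v)
  expect_true(all(sim$de_labels$true_log2fc == 0))
})

test_that("zero dispersion gives Poisson-like counts", {
  cfg <- synthetic_config(seed = 4, de_fraction = 0, nb_dispersion = 0,
                          base_mean_range = c(100, 100),
                          library_size_range = c(1, 1))
  sim <- simulate_counts(cfg, data.frame(circ_id = sprintf("c%05d", 1:5000)))
  x <- as.vector(sim$counts[, 1])
  expect_equal(var(x) / mean(x), 1, tolerance = 0.1)
})

test_that("negative dispersion is a configuration error", {
  expect_error(synthetic_config(nb_dispersion = -0.1), "nb_dispersion")
})

test_that("planted MRE truth is exact and duplicate seeds are rejected", {
  study <- default_study()
  tr <- study$mre$truth
  expect_true(all(tr$site_count >= 1L))
  # every recorded position actually spells the site
  sites <- revcomp(substr(study$mirnas, 2L, 8L))
  for (i in seq_len(nrow(tr))) {
    pos <- as.integer(strsplit(tr$site_positions[i], ",")[[1]])
    expect_length(pos, tr$site_count[i])
    seq <- study$mre$sequences[[tr$rna_id[i]]]
    for (p in pos) {
      expect_identical(substr(seq, p, p + 6L), unname(sites[tr$mirna_id[i]]))
    }
  }
  dup <- c(a = "ACGTACGTACGTACGTACGTAC", b = "TCGTACGTGCGTACGTACGTAC")
  substr(dup["b"], 2, 8) <- substr(dup["a"], 2, 8)
  cfg <- synthetic_config()
  expect_error(plant_mres(cfg, "c1", "m1", dup), "duplicated seed")
})

test_that("over-packed MRE sequences are a generation error", {
  sites <- stats::setNames(revcomp(c("ACGTAGG", "TTTACGC")), c("a", "b"))
  expect_error(
    circlact:::plant_sites_into_sequence(30L, sites, c(a = 2L, b = 2L)),
    "too short")
})
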