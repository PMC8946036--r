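test_that("median-of-ratios size factors match hand-computed values", {
  m <- matrix(c(10, 20, 40, 100,
                20, 40, 80, 200), ncol = 2,
              dimnames = list(paste0("c", 1:4), c("s1", "s2")))
  sf <- estimate_size_factors(m)
  # sample2 = 2 x sample1: geometric means split the factor of two evenly
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  same <- matrix(rep(c(5, 50, 500), 3L), ncol = 3)
  expect_equal(unname(estimate_size_factors(same)), rep(1, 3))

  perm <- m[c(3, 1, 4, 2), ]
  expect_equal(unname(estimate_size_factors(perm)), unname(sf))
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  study <- default_study()
  counts <- study$counts$counts
  ours <- estimate_size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("symmetric observations give p = 1 and the Poisson limit is exact", {
  expect_equal(nb_exact_test(12, 12, 3, 3, 0.1), 1)
  # dispersion -> 0, equal sizes, split (0, 10): binomial(10, 1/2) tails
  expect_equal(nb_exact_test(0, 10, 1, 1, 0), 2 / 1024, tolerance = 1e-12)
  expect_equal(nb_exact_test(10, 0, 1, 1, 0), 2 / 1024, tolerance = 1e-12)
  expect_error(nb_exact_test(1, 1, 1, 1, -0.5), "dispersion")
})

test_that("the exact test equals naive enumeration across conditions", {
  set.seed(77)
  for (rep in 1:60) {
    K <- sample(1:200, 1)
    kA <- sample(0:K, 1)
    sA <- runif(1, 1, 5); sB <- runif(1, 1, 5)
    disp <- sample(c(0, 0.01, 0.1, 0.5), 1)
    ssqA <- runif(1, sA^2 / 3, sA^2)
    ssqB <- runif(1, sB^2 / 3, sB^2)
    expect_equal(nb_exact_test(kA, K - kA, sA, sB, disp, ssqA, ssqB),
                 nb_exact_oracle(kA, K - kA, sA, sB, disp, ssqA, ssqB),
                 tolerance = 1e-12)
  }
})

test_that("dispersion estimation recovers the generating value in the middle", {
  cfg <- synthetic_config(seed = 21, de_fraction = 0, nb_dispersion = 0.1,
                          n_samples_per_group = 10L,
                          base_mean_range = c(100, 300))
  sim <- simulate_counts(cfg, data.frame(circ_id = sprintf("c%04d", 1:500)))
  sf <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersion(sim$counts, sim$samples$group, sf)
  expect_gt(median(disp), 0.05)
  expect_lt(median(disp), 0.2)
})

test_that("Poisson-floor and constant rows give zero raw dispersion", {
  m <- matrix(c(5, 5, 5, 5, 5, 5), nrow = 2)
  disp <- estimate_dispersion(m, c("a", "a", "b"), rep(1, 3),
                              shrink_weight = 0)
  expect_equal(unname(disp), c(0, 0))
})

test_that("run_de flags planted signal with correct direction and ordering", {
  set.seed(5)
  n <- 60
  mu <- rep(150, n)
  lfc <- rep(0, n); lfc[1:6] <- 3; lfc[7:12] <- -3
  counts <- cbind(
    matrix(rnbinom(3 * n, mu = mu * 2^lfc, size = 10), n),
    matrix(rnbinom(3 * n, mu = mu, size = 10), n))
  dimnames(counts) <- list(sprintf("c%02d", 1:n),
                           c(paste0("early_", 1:3), paste0("non_", 1:3)))
  cm <- count_matrix(counts, setNames(rep(c("early_lactation",
                                            "non_lactation"), each = 3),
                                      colnames(counts)))
  de <- run_de(cm)
  up <- de[match(sprintf("c%02d", 1:6), de$circ_id), ]
  down <- de[match(sprintf("c%02d", 7:12), de$circ_id), ]
  expect_true(all(up$direction == "up"))
  expect_true(all(down$direction == "down"))
  expect_true(all(up$significant), all(down$significant))
  expect_true(!is.unsorted(de$adjusted_p))
  expect_true(all(de$adjusted_p >= de$p_value))
})

test_that("doubling all counts leaves fold-change estimates unchanged", {
  study <- default_study()
  cm1 <- count_matrix(study$counts$counts,
                      setNames(study$counts$samples$group,
                               study$counts$samples$sample_id))
  cm2 <- count_matrix(study$counts$counts * 2L,
                      setNames(study$counts$samples$group,
                               study$counts$samples$sample_id))
  de1 <- run_de(cm1); de2 <- run_de(cm2)
  expect_equal(de2$log2_fold_change[match(de1$circ_id, de2$circ_id)],
               de1$log2_fold_change, tolerance = 1e-9)
})

test_that("all-zero rows are kept with p = 1 and undefined fold change", {
  counts <- rbind(c0 = rep(0L, 4L),
                  c1 = c(10L, 12L, 9L, 11L),
                  c2 = c(30L, 28L, 31L, 29L))
  colnames(counts) <- paste0("s", 1:4)
  cm <- count_matrix(counts, setNames(rep(c("early_lactation",
                                            "non_lactation"), each = 2),
                                      colnames(counts)))
  de <- run_de(cm)
  z <- de[de$circ_id == "c0", ]
  expect_equal(z$p_value, 1)
  expect_true(is.na(z$log2_fold_change))
  expect_false(z$significant)
})

test_that("base mean is the mean of size-factor-normalized counts", {
  study <- default_study()
  cm <- count_matrix(study$counts$counts,
                     setNames(study$counts$samples$group,
                              study$counts$samples$sample_id))
  norm <- sweep(cm$counts, 2, cm$size_factors, "/")
  expect_equal(cm$base_mean, rowMeans(norm))
})
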