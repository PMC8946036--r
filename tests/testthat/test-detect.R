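test_that("anchor index enumerates every forward k-mer position", {
  idx <- build_anchor_index(c(chrA = "ACGTACGT"), 4L)
  hits <- circlact:::anchor_hits(idx, "ACGT")
  expect_equal(sort(hits$pos), c(0L, 4L))
  expect_equal(nrow(circlact:::anchor_hits(idx, "TTTT")), 0L)
})

test_that("k-mers never span chromosome boundaries", {
  idx <- build_anchor_index(c(c1 = "AAAAAAAAAACCCC", c2 = "GGGGTTTTTTTTTT"), 14L)
  expect_equal(nrow(circlact:::anchor_hits(idx, "CCCCGGGG")), 0L)
  expect_equal(circlact:::anchor_hits(idx, "AAAAAAAAAACCCC")$chrom, "c1")
  expect_error(build_anchor_index(c(c1 = "ACGT"), 10L), "exceeds")
})

test_that("colinear and cross-chromosome reads yield no back-splice", {
  study <- default_study()
  idx <- build_anchor_index(study$genome, 20L)
  cfg <- detector_config()
  lin <- genome_sub(study$genome, "chr1", 500L, 600L)
  expect_identical(detect_backsplice(lin, idx, study$genome, cfg)$status,
                   "no_candidate")
  chim <- paste0(genome_sub(study$genome, "chr1", 5000L, 5050L),
                 genome_sub(study$genome, "chr2", 800L, 850L))
  expect_identical(detect_backsplice(chim, idx, study$genome, cfg)$status,
                   "no_candidate")
  expect_identical(detect_backsplice(strrep("A", 30L), idx, study$genome,
                                     cfg)$status, "too_short")
})

test_that("planted junction reads are detected at exact planted coordinates", {
  study <- default_study()
  idx <- build_anchor_index(study$genome, 20L)
  cfg <- detector_config()
  for (i in c(1L, 10L, 25L, 50L)) {
    circ <- study$circles[i, ]
    cs <- circlact:::circle_sequence(study$genome, circ)
    leff <- min(100L, nchar(cs))
    b <- 30L
    rd <- paste0(substr(cs, nchar(cs) - b + 1L, nchar(cs)),
                 substr(cs, 1L, leff - b))
    res <- detect_backsplice(rd, idx, study$genome, cfg)
    expect_identical(res$status, "candidate")
    expect_equal(res$start, circ$start)
    expect_equal(res$end, circ$end)
    expect_identical(res$strand, circ$strand)
    expect_identical(res$splice_signal, "GT-AG")
  }
})

test_that("call aggregation enforces the junction-read threshold", {
  study <- default_study()
  idx <- build_anchor_index(study$genome, 20L)
  circ <- study$circles[1, ]
  cs <- circlact:::circle_sequence(study$genome, circ)
  rd <- paste0(substr(cs, nchar(cs) - 29L, nchar(cs)), substr(cs, 1L, 70L))
  one <- list(id = "r1", sequence = rd, quality = list(rep(40L, 100L)))
  res1 <- call_circrnas(one, idx, study$genome,
                        detector_config(min_junction_reads = 2L))
  expect_equal(nrow(res1$calls), 0L)
  two <- list(id = c("r1", "r2"), sequence = c(rd, rd),
              quality = list(rep(40L, 100L), rep(40L, 100L)))
  res2 <- call_circrnas(two, idx, study$genome,
                        detector_config(min_junction_reads = 2L))
  expect_equal(nrow(res2$calls), 1L)
  expect_equal(res2$calls$junction_reads, 2L)
})

test_that("per-sample support is preserved in the sample-count table", {
  det <- default_detection()
  study <- default_study()
  expect_identical(colnames(det$sample_counts), names(study$reads))
  expect_equal(rowSums(det$sample_counts),
               stats::setNames(det$calls$junction_reads, det$calls$circ_id))
  # every junction read id names the circle it was simulated from
  for (cid in names(det$read_ids)[c(1L, 20L)]) {
    call <- det$calls[det$calls$circ_id == cid, ]
    truth <- study$circles[study$circles$chrom == call$chrom &
                             study$circles$start == call$start &
                             study$circles$end == call$end, ]
    src <- vapply(strsplit(det$read_ids[[cid]], "|", fixed = TRUE),
                  `[[`, character(1L), 2L)
    expect_true(all(src == truth$circ_id))
  }
})

test_that("reported splice signals re-read from the genome match", {
  det <- default_detection()
  study <- default_study()
  for (i in seq_len(nrow(det$calls))) {
    call <- det$calls[i, ]
    expect_identical(
      circlact:::splice_signal_at(study$genome, call$chrom, call$start,
                                  call$end, call$strand),
      call$splice_signal)
  }
})
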