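test_that("seed matching counts greedy non-overlapping occurrences", {
  mir <- c(miR_x = "CAGTACGTAGCTAGCTAGCTAG")   # seed = AGTACGT
  site <- revcomp("AGTACGT")                   # ACGTACT
  rna <- c(r0 = strrep("G", 40),
           r1 = paste0(strrep("G", 10), site, strrep("C", 10)),
           r3 = paste0(site, "GG", site, strrep("A", 8), site))
  res <- predict_mres(rna, mir, rna_class = "circRNA")
  expect_false("r0" %in% res$rna_id)
  expect_equal(res$site_count[res$rna_id == "r1"], 1L)
  expect_equal(res$site_count[res$rna_id == "r3"], 3L)
  # overlapping tandem occurrences are counted greedily left to right:
  # seed TGTGTGT gives site ACACACA; (AC)x8 holds 5 overlapping copies
  # (positions 1,3,5,7,9) but only 2 non-overlapping ones (1 and 9)
  mir_tandem <- c(miR_t = paste0("C", "TGTGTGT", strrep("A", 14)))
  hit <- predict_mres(c(t1 = strrep("AC", 8)), mir_tandem)
  expect_equal(hit$site_count, 2L)
  expect_identical(hit$site_positions, "1,9")
  expect_error(predict_mres(rna, c(short = "ACGTA")), "shorter")
})

test_that("planted multiplicities are recovered exactly", {
  study <- default_study()
  pred <- predict_mres(study$mre$sequences, study$mirnas,
                       rna_class = study$mre$rna_class)
  truth <- study$mre$truth
  merged <- merge(pred, truth, by = c("rna_id", "mirna_id"), all = TRUE)
  expect_true(!any(is.na(merged$site_count.x)))
  expect_true(!any(is.na(merged$site_count.y)))
  expect_equal(merged$site_count.x, merged$site_count.y)
  expect_identical(merged$site_positions.x, merged$site_positions.y)
})

test_that("the ceRNA score is the shared fraction of circRNA-side sites", {
  sites <- c(miR_a = 3L, miR_b = 2L, miR_c = 1L)
  expect_equal(cerna_score(sites, c("miR_a", "miR_b", "miR_c")), 1)
  expect_equal(cerna_score(sites, character(0)), 0)
  expect_equal(cerna_score(sites, c("miR_a", "miR_c")), 4 / 6)
  # mRNA-side counts never enter the score
  expect_equal(cerna_score(sites, c("miR_a", "miR_c", "miR_zzz")), 4 / 6)
  expect_error(cerna_score(c(miR_a = 0L), "miR_a"), "no miRNA response")
})

test_that("hypergeometric spot values match binomial-coefficient arithmetic", {
  expect_equal(shared_mirna_pvalue(10, 4, 5, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(shared_mirna_pvalue(20, 6, 8, 5), 700 / 38760,
               tolerance = 1e-12)
  expect_equal(shared_mirna_pvalue(10, 4, 5, 0), 1)
  expect_error(shared_mirna_pvalue(10, 4, 5, 5), "m_c")
  expect_error(shared_mirna_pvalue(10, 11, 5, 2), "M_T")
})

test_that("p-value is non-increasing in the shared count", {
  for (M in c(10, 25, 40)) {
    p <- vapply(0:8, function(mc) shared_mirna_pvalue(M, 8, 9, mc),
                numeric(1))
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("the network filter retains exactly the qualifying pairs", {
  # construct an MRE table with known shared structure
  mre <- rbind(
    data.frame(rna_id = "circA", rna_class = "circRNA",
               mirna_id = paste0("m", 1:4), site_count = c(2L, 1L, 1L, 1L),
               site_positions = "1"),
    data.frame(rna_id = "circB", rna_class = "circRNA",
               mirna_id = paste0("m", 1:2), site_count = 1L,
               site_positions = "1"),
    data.frame(rna_id = "geneX", rna_class = "mRNA",
               mirna_id = paste0("m", 1:4), site_count = 1L,
               site_positions = "1"),
    data.frame(rna_id = "geneY", rna_class = "mRNA",
               mirna_id = paste0("m", c(1:2, 5:8)), site_count = 1L,
               site_positions = "1"))
  net <- build_cerna_network(mre, mirna_universe = paste0("m", 1:10),
                             min_shared = 3L, max_p = 0.05)
  pairs <- net$pairs
  expect_equal(nrow(pairs), 4L)
  # circA-geneX: m_c = 4 of M_T = 10, p small -> retained
  ax <- pairs[pairs$circ_id == "circA" & pairs$mrna_id == "geneX", ]
  expect_true(ax$retained)
  expect_equal(ax$m_c, 4L)
  expect_equal(ax$cerna_score, 1)
  expect_equal(ax$p_value, hyper_tail_oracle(10, 4, 4, 4), tolerance = 1e-12)
  # circB-geneX shares only 2 miRNAs -> excluded regardless of p
  bx <- pairs[pairs$circ_id == "circB" & pairs$mrna_id == "geneX", ]
  expect_false(bx$retained)
  # every retained pair satisfies both thresholds
  expect_true(all(net$retained$m_c >= 3L & net$retained$p_value <= 0.05))
  # ranked by score desc, then shared count desc
  expect_true(!is.unsorted(-net$retained$cerna_score))
})

test_that("boundary pairs at m_c = 3 and p = 0.05 are retained", {
  # a synthetic pair table exercised through the filter logic directly
  mre <- rbind(
    data.frame(rna_id = "c1", rna_class = "circRNA", mirna_id = paste0("m", 1:3),
               site_count = 1L, site_positions = "1"),
    data.frame(rna_id = "g1", rna_class = "mRNA", mirna_id = paste0("m", 1:3),
               site_count = 1L, site_positions = "1"))
  # choose M_T so that p(m_c = 3) is exactly the full-overlap tail
  net <- build_cerna_network(mre, mirna_universe = paste0("m", 1:30),
                             min_shared = 3L,
                             max_p = hyper_tail_oracle(30, 3, 3, 3))
  expect_equal(nrow(net$retained), 1L)
  expect_equal(net$retained$m_c, 3L)
})

test_that("network nodes and edges cover exactly the retained pairs", {
  study <- default_study()
  pred <- predict_mres(study$mre$sequences, study$mirnas,
                       rna_class = study$mre$rna_class)
  net <- build_cerna_network(pred, mirna_universe = names(study$mirnas))
  g <- net$graph
  if (nrow(net$retained)) {
    ed <- igraph::as_data_frame(g, what = "edges")
    cerna_edges <- ed[ed$relation == "ceRNA", ]
    expect_setequal(paste(cerna_edges$from, cerna_edges$to),
                    paste(net$retained$circ_id, net$retained$mrna_id))
    expect_equal(sum(igraph::degree(g) == 0), 0)
    types <- igraph::V(g)$type
    expect_true(all(types %in% c("circRNA", "miRNA", "mRNA")))
  } else {
    expect_equal(igraph::vcount(g), 0)
  }
})

test_that("a planted strong ceRNA pair outranks random decoys", {
  set.seed(303)
  mirnas <- paste0("m", 1:20)
  rows <- list()
  # strong pair: circ_hit and gene_hit share 6 miRNAs, all circ sites shared
  shared <- mirnas[1:6]
  rows[[1]] <- data.frame(rna_id = "circ_hit", rna_class = "circRNA",
                          mirna_id = shared, site_count = 2L,
                          site_positions = "1")
  rows[[2]] <- data.frame(rna_id = "gene_hit", rna_class = "mRNA",
                          mirna_id = shared, site_count = 1L,
                          site_positions = "1")
  for (i in 1:6) {
    rows[[length(rows) + 1L]] <- data.frame(
      rna_id = paste0("circ_dec", i), rna_class = "circRNA",
      mirna_id = sample(mirnas, 8), site_count = 1L, site_positions = "1")
    rows[[length(rows) + 1L]] <- data.frame(
      rna_id = paste0("gene_dec", i), rna_class = "mRNA",
      mirna_id = sample(mirnas, 8), site_count = 1L, site_positions = "1")
  }
  net <- build_cerna_network(do.call(rbind, rows), mirna_universe = mirnas)
  expect_gt(nrow(net$retained), 0)
  expect_identical(net$retained$circ_id[1], "circ_hit")
  expect_identical(net$retained$mrna_id[1], "gene_hit")
})

test_that("GraphML export round-trips through igraph", {
  mre <- rbind(
    data.frame(rna_id = "c1", rna_class = "circRNA",
               mirna_id = paste0("m", 1:3), site_count = 1L,
               site_positions = "1"),
    data.frame(rna_id = "g1", rna_class = "mRNA",
               mirna_id = paste0("m", 1:3), site_count = 1L,
               site_positions = "1"))
  net <- build_cerna_network(mre, mirna_universe = paste0("m", 1:20))
  prefix <- file.path(withr::local_tempdir(), "net")
  write_cerna_network(net, prefix)
  g <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), igraph::vcount(net$graph))
  expect_equal(igraph::ecount(g), igraph::ecount(net$graph))
  nodes <- read_tsv(paste0(prefix, "_nodes.tsv"))
  expect_setequal(nodes$node, igraph::V(net$graph)$name)
})
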