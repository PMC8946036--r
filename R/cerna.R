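#' Predict miRNA response elements by seed matching
#'
#' A site is an exact reverse-complement match of the miRNA seed (by
#' default positions 2-8, a 7-mer) in the RNA sequence; occurrences are
#' counted greedily left to right without overlap.  `U` in miRNA
#' sequences is treated as `T`.  Rows are emitted only for pairs with at
#' least one site.
#'
#' @param rna_seqs Named character vector of RNA sequences.
#' @param mirna_seqs Named character vector of mature miRNA sequences.
#' @param rna_class Single class label or named vector
#'   (`circRNA`/`mRNA`) for the RNAs.
#' @param seed_span Two integers, the 1-based inclusive seed positions on
#'   the miRNA (default `c(2, 8)`).
#' @return Data frame `rna_id`, `rna_class`, `mirna_id`, `site_count`,
#'   `site_positions` (1-based, comma-separated).
#' @export
predict_mres <- function(rna_seqs, mirna_seqs, rna_class = "circRNA",
                         seed_span = c(2L, 8L)) {
  mirna_seqs <- chartr("Uu", "TT", toupper(mirna_seqs))
  short <- nchar(mirna_seqs) < seed_span[2]
  if (any(short)) {
    stop("miRNA(s) shorter than the seed span: ",
         paste(names(mirna_seqs)[short], collapse = ", "))
  }
  seeds <- substr(mirna_seqs, seed_span[1], seed_span[2])
  sites <- revcomp(seeds)
  if (is.null(names(rna_class))) {
    rna_class <- stats::setNames(rep_len(rna_class, length(rna_seqs)),
                                 names(rna_seqs))
  }
  rows <- list()
  for (rid in names(rna_seqs)) {
    seq <- toupper(rna_seqs[[rid]])
    for (j in seq_along(mirna_seqs)) {
      hits <- gregexpr(sites[j], seq, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        rna_id = rid, rna_class = unname(rna_class[rid]),
        mirna_id = names(mirna_seqs)[j], site_count = length(hits),
        site_positions = paste(as.integer(hits), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(rna_id = character(0), rna_class = character(0),
                      mirna_id = character(0), site_count = integer(0),
                      site_positions = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ceRNA score of one circRNA-mRNA pair
#'
#' The score is the fraction of the circRNA's miRNA response elements
#' that belong to miRNAs shared with the mRNA: the summed site count over
#' shared miRNAs divided by the summed site count over all miRNAs
#' targeting the circRNA.  Only circRNA-side sites enter the score.
#'
#' @param circ_sites Named integer vector: site counts per miRNA on the
#'   circRNA (must contain at least one site overall).
#' @param shared_mirnas Character vector of miRNA ids shared with the
#'   mRNA.
#' @return Score in `[0, 1]`.
#' @export
cerna_score <- function(circ_sites, shared_mirnas) {
  total <- sum(circ_sites)
  if (total <= 0) {
    stop("circRNA has no miRNA response elements; pair is not a candidate")
  }
  shared <- sum(circ_sites[names(circ_sites) %in% shared_mirnas])
  shared / total
}

#' Hypergeometric shared-miRNA p-value
#'
#' Upper-tail probability of observing at least `m_c` shared miRNAs when
#' `m_p` of `M_T` miRNAs target the mRNA and `m_n` target the circRNA:
#' `p = sum_{i=m_c}^{min(m_p, m_n)} C(m_n, i) C(M_T - m_n, m_p - i) /
#' C(M_T, m_p)`, evaluated in log space.
#'
#' @param M_T Number of miRNAs in the analysis universe.
#' @param m_p Number of miRNAs targeting the mRNA.
#' @param m_n Number of miRNAs targeting the circRNA.
#' @param m_c Number of shared miRNAs.
#' @return Probability in `[0, 1]`.
#' @export
shared_mirna_pvalue <- function(M_T, m_p, m_n, m_c) {
  if (m_p > M_T || m_n > M_T) stop("m_p and m_n cannot exceed M_T")
  if (m_c > min(m_p, m_n)) stop("m_c cannot exceed min(m_p, m_n)")
  if (m_c < 0) stop("m_c must be >= 0")
  if (m_c == 0) return(1)
  i <- m_c:min(m_p, m_n)
  lt <- lchoose(m_n, i) + lchoose(M_T - m_n, m_p - i) - lchoose(M_T, m_p)
  min(1, exp(logsumexp(lt)))
}

#' Score, test and filter circRNA-mRNA ceRNA pairs; build the network
#'
#' Every circRNA x mRNA pair sharing at least one targeting miRNA is
#' scored ([cerna_score()]) and tested ([shared_mirna_pvalue()]).  Pairs
#' with fewer than `min_shared` shared miRNAs or a p-value above `max_p`
#' are filtered out (the wording is strict, so `m_c = min_shared` and
#' `p = max_p` are retained).  Survivors are ranked by score (desc), then
#' shared-miRNA count (desc), then pair id.
#'
#' @param mre_table MRE table from [predict_mres()] covering both RNA
#'   classes.
#' @param mirna_universe miRNA ids defining `M_T`; defaults to the
#'   distinct miRNAs in `mre_table`, but should be the full set supplied
#'   to the run.
#' @param min_shared Minimum shared-miRNA count (default 3).
#' @param max_p Maximum p-value (default 0.05).
#' @param adjust_p Apply BH adjustment before filtering (default FALSE,
#'   matching filtering on raw p).
#' @return List with `pairs` (all candidate pairs with `M_T`, `m_p`,
#'   `m_n`, `m_c`, `shared_mirnas`, `cerna_score`, `p_value`,
#'   `retained`), `retained` (filtered, ranked) and `graph` (an
#'   [igraph::igraph] with typed nodes, circRNA-miRNA and miRNA-mRNA
#'   targeting edges of retained pairs, and scored circRNA-mRNA edges).
#' @export
build_cerna_network <- function(mre_table, mirna_universe = NULL,
                                min_shared = 3L, max_p = 0.05,
                                adjust_p = FALSE) {
  circ <- mre_table[mre_table$rna_class == "circRNA", , drop = FALSE]
  mrna <- mre_table[mre_table$rna_class == "mRNA", , drop = FALSE]
  if (!nrow(mrna)) {
    warning("no mRNA rows in the MRE table; empty network")
  }
  if (is.null(mirna_universe)) mirna_universe <- unique(mre_table$mirna_id)
  M_T <- length(mirna_universe)
  circ_sites <- split(stats::setNames(circ$site_count, circ$mirna_id),
                      circ$rna_id)
  mrna_sets <- split(mrna$mirna_id, mrna$rna_id)
  rows <- list()
  for (cid in names(circ_sites)) {
    cs <- circ_sites[[cid]]
    for (mid in names(mrna_sets)) {
      sh <- intersect(names(cs), mrna_sets[[mid]])
      if (!length(sh)) next
      m_n <- length(cs); m_p <- length(mrna_sets[[mid]]); m_c <- length(sh)
      rows[[length(rows) + 1L]] <- data.frame(
        circ_id = cid, mrna_id = mid, M_T = M_T, m_p = m_p, m_n = m_n,
        m_c = m_c, shared_mirnas = paste(sort(sh), collapse = ","),
        cerna_score = cerna_score(cs, sh),
        p_value = shared_mirna_pvalue(M_T, m_p, m_n, m_c),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(circ_id = character(0), mrna_id = character(0),
               M_T = integer(0), m_p = integer(0), m_n = integer(0),
               m_c = integer(0), shared_mirnas = character(0),
               cerna_score = numeric(0), p_value = numeric(0))
  p_for_filter <- if (adjust_p) stats::p.adjust(pairs$p_value, "BH")
                  else pairs$p_value
  # p == max_p is retained; the tolerance guards the equality against
  # floating-point noise in the log-space tail sum
  pairs$retained <- pairs$m_c >= min_shared &
    p_for_filter <= max_p * (1 + 1e-9)
  retained <- pairs[pairs$retained, , drop = FALSE]
  pair_id <- paste(retained$circ_id, retained$mrna_id, sep = "|")
  ord <- order(-retained$cerna_score, -retained$m_c, pair_id)
  retained <- retained[ord, , drop = FALSE]
  rownames(pairs) <- rownames(retained) <- NULL
  graph <- cerna_graph(retained)
  list(pairs = pairs, retained = retained, graph = graph)
}

# Typed igraph of the retained ceRNA pairs.
cerna_graph <- function(retained) {
  if (!nrow(retained)) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(g)
  }
  edges <- list()
  for (i in seq_len(nrow(retained))) {
    sh <- strsplit(retained$shared_mirnas[i], ",", fixed = TRUE)[[1L]]
    edges[[length(edges) + 1L]] <- data.frame(
      from = retained$circ_id[i], to = retained$mrna_id[i],
      relation = "ceRNA", cerna_score = retained$cerna_score[i],
      p_value = retained$p_value[i], stringsAsFactors = FALSE)
    edges[[length(edges) + 1L]] <- data.frame(
      from = retained$circ_id[i], to = sh, relation = "circRNA-miRNA",
      cerna_score = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE)
    edges[[length(edges) + 1L]] <- data.frame(
      from = sh, to = retained$mrna_id[i], relation = "miRNA-mRNA",
      cerna_score = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE)
  }
  ed <- unique(do.call(rbind, edges))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  type <- ifelse(igraph::V(g)$name %in% retained$circ_id, "circRNA",
                 ifelse(igraph::V(g)$name %in% retained$mrna_id, "mRNA",
                        "miRNA"))
  igraph::V(g)$type <- type
  g
}

#' Export a ceRNA network for Cytoscape
#'
#' Writes GraphML plus node/edge TSVs loadable in Cytoscape.
#'
#' @param network Result of [build_cerna_network()].
#' @param prefix Output path prefix; creates `<prefix>.graphml`,
#'   `<prefix>_nodes.tsv`, `<prefix>_edges.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_cerna_network <- function(network, prefix) {
  g <- network$graph
  write_graphml(g, paste0(prefix, ".graphml"))
  nodes <- data.frame(node = igraph::V(g)$name,
                      type = if (igraph::vcount(g)) igraph::V(g)$type
                             else character(0))
  ed <- igraph::as_data_frame(g, what = "edges")
  write_tsv(nodes, paste0(prefix, "_nodes.tsv"))
  write_tsv(ed, paste0(prefix, "_edges.tsv"))
  invisible(prefix)
}
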