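#' Read a gene-set term map
#'
#' Accepts either a two-column TSV (`term_id<TAB>gene_id`, optional
#' header) or GMT (`term_id<TAB>description<TAB>gene...` per line).
#'
#' @param path Input path.
#' @param format `"tsv"` or `"gmt"`.
#' @return Named list of character vectors (term -> member genes).
#' @export
read_term_map <- function(path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    terms <- lapply(lines, function(x) unique(x[-(1:2)]))
    names(terms) <- vapply(lines, `[[`, character(1L), 1L)
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (identical(tolower(df[1, 1]), "term_id")) df <- df[-1, , drop = FALSE]
    terms <- split(df[[2]], df[[1]])
    terms <- lapply(terms, unique)
  }
  if (any(lengths(terms) == 0L)) stop("term map contains empty term(s)")
  terms
}

#' Hypergeometric over-representation test for gene sets
#'
#' For each term, tests whether the study genes over-represent the term's
#' members relative to the universe, using the hypergeometric upper tail
#' (the same kernel as the shared-miRNA ceRNA test: `M_T = N`,
#' `m_n = K`, `m_p = n`, `m_c = k`).  P-values are BH-adjusted and
#' results sorted by p.
#'
#' @param study_genes Character vector of genes of interest; must be a
#'   subset of the universe.
#' @param term_map Named list of member-gene vectors (see
#'   [read_term_map()]).
#' @param universe Background gene set; defaults to all genes bearing at
#'   least one annotation in `term_map`.
#' @return Data frame `term_id`, `k`, `n`, `K`, `N`, `p_value`,
#'   `adjusted_p`, sorted by `p_value`.
#' @export
enrich_terms <- function(study_genes, term_map, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(term_map))
  study_genes <- unique(study_genes)
  outside <- setdiff(study_genes, universe)
  if (length(outside)) {
    stop("study gene(s) outside the universe: ",
         paste(outside, collapse = ", "))
  }
  N <- length(universe)
  n <- length(study_genes)
  rows <- lapply(names(term_map), function(tid) {
    members <- intersect(term_map[[tid]], universe)
    K <- length(members)
    k <- length(intersect(study_genes, members))
    p <- shared_mirna_pvalue(M_T = N, m_p = n, m_n = K, m_c = k)
    data.frame(term_id = tid, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}
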