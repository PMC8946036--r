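#' Run the full circRNA analysis pipeline on a synthetic study
#'
#' Stages run in order: synthetic-study generation, read preprocessing,
#' back-splice detection, classification/characterization, differential
#' junction-count testing, MRE prediction and ceRNA network construction,
#' and (when a term map is supplied) gene-set over-representation of the
#' parent genes of significant circRNAs.  Every output is a plain-text
#' file under `outdir`; a JSON manifest records the seed, a config hash
#' and per-stage row counts, and two runs with the same config are
#' byte-identical.
#'
#' @param config A [synthetic_config()]; its `seed` drives every stage.
#' @param outdir Output directory.
#' @param qc_cfg,det_cfg Stage configurations.
#' @param lfc_threshold,alpha Differential-expression thresholds.
#' @param min_shared,max_p ceRNA network filter thresholds.
#' @param term_map Optional named list of gene sets for the enrichment
#'   stage.
#' @return List with all stage results plus `manifest`.
#' @export
run_pipeline <- function(config = synthetic_config(), outdir,
                         qc_cfg = qc_config(),
                         det_cfg = detector_config(
                           anchor_length = config$anchor_length),
                         lfc_threshold = 1, alpha = 0.05,
                         min_shared = 3L, max_p = 0.05,
                         term_map = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  synth_dir <- file.path(outdir, "synth")
  study <- synthesize_study(config, synth_dir)

  qc_out <- lapply(study$reads, run_qc, config = qc_cfg)
  clean_reads <- lapply(qc_out, `[[`, "reads")
  qc_report <- lapply(qc_out, `[[`, "report")
  jsonlite::write_json(qc_report, file.path(outdir, "qc_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  index <- build_anchor_index(study$genome, det_cfg$anchor_length)
  det <- call_circrnas(clean_reads, index, study$genome, det_cfg)
  write_circ_calls(det, file.path(outdir, "circ_calls.bed"),
                   file.path(outdir, "circ_calls.tsv"))

  ann <- annotate_circs(det$calls, study$models, study$genome)
  write_tsv(ann, file.path(outdir, "circ_annotation.tsv"))
  summ <- summarize_circs(ann, det$calls)
  jsonlite::write_json(
    list(n_circ = summ$n_circ, mean_length = summ$mean_length,
         per_chromosome = as.list(summ$per_chromosome),
         length_hist = as.list(summ$length_hist),
         exon_hist = as.list(summ$exon_hist),
         gc_hist = as.list(summ$gc_hist),
         category_percent = as.list(round(summ$category_percent, 4)),
         splice_signal = as.list(summ$splice_signal)),
    file.path(outdir, "characterization.json"),
    auto_unbox = TRUE, pretty = TRUE)

  cm <- count_matrix(study$counts$counts,
                     stats::setNames(study$counts$samples$group,
                                     study$counts$samples$sample_id))
  de <- run_de(cm, lfc_threshold = lfc_threshold, alpha = alpha)
  write_tsv(de, file.path(outdir, "de_results.tsv"))

  mre_pred <- predict_mres(study$mre$sequences, study$mirnas,
                           rna_class = study$mre$rna_class)
  write_tsv(mre_pred, file.path(outdir, "mre_table.tsv"))
  net <- build_cerna_network(mre_pred,
                             mirna_universe = names(study$mirnas),
                             min_shared = min_shared, max_p = max_p)
  write_tsv(net$pairs, file.path(outdir, "cerna_pairs.tsv"))
  write_tsv(net$retained, file.path(outdir, "cerna_retained.tsv"))
  write_cerna_network(net, file.path(outdir, "cerna_network"))

  enr <- NULL
  if (!is.null(term_map)) {
    sig <- de$circ_id[de$significant]
    truth_ann <- annotate_circs(study$circles, study$models)
    parents <- unique(stats::na.omit(
      truth_ann$parent_gene[truth_ann$circ_id %in% sig]))
    if (length(parents)) {
      enr <- enrich_terms(parents, term_map)
      write_tsv(enr, file.path(outdir, "enrichment.tsv"))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("circlact")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = list(
      synth = list(circles = nrow(study$circles),
                   samples = length(study$reads),
                   reads_per_sample = vapply(study$reads,
                                             function(r) length(r$id), 0L)),
      qc = lapply(qc_report, `[[`, "surviving_reads"),
      detect = list(calls = nrow(det$calls),
                    skipped = as.list(det$skipped)),
      annotate = list(n = nrow(ann)),
      de = list(tested = nrow(de), significant = sum(de$significant)),
      cerna = list(candidate_pairs = nrow(net$pairs),
                   retained_pairs = nrow(net$retained)),
      enrich = if (is.null(enr)) "skipped" else list(terms = nrow(enr))
    )
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(study = study, qc = qc_report, detection = det,
                 annotation = ann, summary = summ, de = de,
                 mre = mre_pred, network = net, enrichment = enr,
                 manifest = manifest))
}

# Stable hash of a config: md5 of its deparsed canonical form.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [synthetic_config()]; unknown keys are an
#' error so typos fail fast.
#'
#' @param path YAML file path.
#' @return A [synthetic_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(synthetic_config, vals)
}
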