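# End-to-end orchestration: simulate/read -> features -> markers -> model ->
# enrichment -> kaks, with a hashed manifest for reproducibility.

#' Pipeline configuration
#'
#' Collects the thresholds of the whole workflow: strain filters (mean
#' relative abundance above half a percent, mean depth > 10x), the
#' importance cutoff
#' (0.01), 10-fold cross-validation, the enrichment level (0.05), and
#' either a simulation config or paths to real inputs.
#'
#' @param sim A [sim_config] for synthetic runs, or `NULL` when `paths` is
#'   given.
#' @param paths Named list for file-based runs: `gff`, `fasta`, `vcf_dir`
#'   (one VCF per sample, named `<sample>.vcf`), `abundance`, `depth`,
#'   `metadata`.
#' @param min_abundance,min_depth Strain filter thresholds.
#' @param importance_cutoff Marker panel importance cutoff.
#' @param folds Cross-validation folds.
#' @param alpha Enrichment significance level.
#' @param ntree Trees per forest.
#' @param qual_min,dp_min Site filters applied when reading VCFs.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            min_abundance = 0.005, min_depth = 10,
                            importance_cutoff = 0.01, folds = 10L,
                            alpha = 0.05, ntree = 500L, qual_min = 20,
                            dp_min = 10, seed = 1L) {
  if (is.null(sim) && is.null(paths))
    stopf("either a simulation config or input paths are required")
  if (min_abundance < 0 || min_depth < 0 || importance_cutoff < 0)
    stopf("thresholds must be nonnegative")
  structure(list(sim = sim, paths = paths, min_abundance = min_abundance,
                 min_depth = min_depth,
                 importance_cutoff = importance_cutoff,
                 folds = as.integer(folds), alpha = alpha,
                 ntree = as.integer(ntree), qual_min = qual_min,
                 dp_min = dp_min, seed = as.integer(seed)),
            class = "pipeline_config")
}

log_stage <- function(log, msg) {
  cat(msg, "\n", file = log, append = TRUE, sep = "")
  message(format(Sys.time(), "%H:%M:%S "), msg)
}

#' Run the discovery workflow end to end
#'
#' Stages: (1) obtain inputs - either emit a synthetic cohort and read its
#' files back through the package's own readers, or read the configured
#' real inputs; (2) build the normalized feature matrix (strain filter,
#' SNV-to-gene assignment, abundance x depth normalization); (3) fit the
#' marker model (ranking, panel, CV curve, final classifier, out-of-bag
#' ROC); (4) Wilcoxon enrichment of every gene; (5) Ka/Ks of the selected
#' panel. All outputs are written to `outdir` together with
#' `manifest.json` recording an md5 for every artifact; reruns with the
#' same config are byte-identical.
#'
#' @param config A [pipeline_config].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the fitted model (`fit`), `features`,
#'   `enrichment`, `kaks` and the `manifest`.
#' @export
run_discovery <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(outdir, "run.log")
  cat("", file = log)

  if (!is.null(config$sim)) {
    log_stage(log, "stage simulate: generating synthetic cohort")
    genomes <- simulate_genomes(config$sim)
    sc <- simulate_cohort(config$sim, genomes, detail = "snvs",
                          outdir = file.path(outdir, "inputs"))
    paths <- list(gff = sc$files$gff, fasta = sc$files$fasta,
                  abundance = sc$files$abundance, depth = sc$files$depth,
                  metadata = sc$files$metadata,
                  vcfs = sc$files$vcfs)
  } else {
    paths <- config$paths
    vcf_files <- list.files(paths$vcf_dir, pattern = "\\.vcf(\\.gz)?$",
                            full.names = TRUE)
    if (!length(vcf_files)) stopf("io stage: no VCF files in %s",
                                  paths$vcf_dir)
    paths$vcfs <- setNames(vcf_files,
                           sub("\\.vcf(\\.gz)?$", "", basename(vcf_files)))
  }
  for (p in c("gff", "fasta", "abundance", "depth", "metadata"))
    if (is.null(paths[[p]]) || !file.exists(paths[[p]]))
      stopf("io stage: missing input '%s'", p)

  log_stage(log, "stage io: reading annotation, tables and VCFs")
  genes <- read_gene_models(paths$gff, paths$fasta)
  cohort <- read_cohort_tables(paths$abundance, paths$depth, paths$metadata)
  snv_list <- lapply(names(paths$vcfs), function(s)
    read_snv_vcf(paths$vcfs[[s]], s, qual_min = config$qual_min,
                 dp_min = config$dp_min, contigs = unique(genes$strain)))
  snvs <- do.call(rbind, snv_list)
  class(snvs) <- c("snv_records", "data.frame")

  log_stage(log, "stage features: strain filter + normalization")
  feats <- build_features(snvs, genes, cohort,
                          min_abundance = config$min_abundance,
                          min_depth = config$min_depth)

  log_stage(log, "stage markers: random-forest ranking + CV curve")
  fit <- fit_marker_model(feats, cutoff = config$importance_cutoff,
                          folds = config$folds, ntree = config$ntree,
                          seed = config$seed)

  log_stage(log, "stage enrichment: Wilcoxon rank-sum per gene")
  enr <- enrich_panel(feats, alpha = config$alpha)

  log_stage(log, "stage kaks: selection analysis of the panel")
  panel_genes <- feats$genes[feats$genes$gene_id %in% fit$selected, ,
                             drop = FALSE]
  class(panel_genes) <- c("gene_models", "data.frame")
  kk <- kaks_for_genes(panel_genes, snvs)

  log_stage(log, "stage write: tables, reports, manifest")
  out <- c(write_features_tsv(feats, outdir, config),
           write_fit_outputs(fit, outdir),
           write_tsv(enr, file.path(outdir, "enrichment.tsv")),
           write_tsv(kk, file.path(outdir, "kaks.tsv")))
  saveRDS(fit, file.path(outdir, "model.rds"))

  manifest <- list(
    seed = config$seed,
    thresholds = config[c("min_abundance", "min_depth", "importance_cutoff",
                          "folds", "alpha", "ntree", "qual_min", "dp_min")],
    outputs = file_hashes(c(out, log), outdir))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fit = fit, features = feats, enrichment = enr, kaks = kk,
                 manifest = manifest, outdir = outdir))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_features_tsv <- function(feats, outdir, config) {
  fpath <- file.path(outdir, "features.tsv")
  write_sample_matrix(feats$values, fpath)
  side <- list(n_samples = nrow(feats$values), n_genes = ncol(feats$values),
               nonredundant_total = feats$nonredundant_total,
               min_abundance = config$min_abundance,
               min_depth = config$min_depth,
               qual_min = config$qual_min, dp_min = config$dp_min)
  jpath <- file.path(outdir, "features.json")
  jsonlite::write_json(side, jpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(fpath, jpath)
}

write_fit_outputs <- function(fit, outdir) {
  ppath <- file.path(outdir, "panel.tsv")
  write_tsv(data.frame(gene_id = fit$panel$ranking,
                       importance = unname(fit$panel$scores),
                       selected = fit$panel$ranking %in% fit$selected),
            ppath)
  cpath <- file.path(outdir, "cv_curve.tsv")
  write_tsv(data.frame(n_genes = fit$curve$feature_counts,
                       cv_error = unname(fit$curve$error)), cpath)
  rpath <- file.path(outdir, "within_report.json")
  rep <- fit$within_report
  jsonlite::write_json(list(auc = rep$auc, mode = rep$mode,
                            n_positive = rep$n_positive,
                            n_negative = rep$n_negative,
                            train_cohort = rep$train_cohort),
                       rpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(ppath, cpath, rpath)
}

file_hashes <- function(paths, root) {
  h <- tools::md5sum(paths)
  names(h) <- sub("^/", "", sub(normalizePath(root), "", normalizePath(paths),
                                fixed = TRUE))
  as.list(h)
}

#' Transfer a fitted model to an untouched cohort
#'
#' Scores a new cohort with a discovery-stage model and reports ROC/AUC.
#' The evaluation cohort plays no role in training; scores are computed
#' before labels are consulted.
#'
#' @param fit An `snv_marker_fit`, or the output directory of a
#'   [run_discovery()] run (its `model.rds` is loaded).
#' @param x Evaluation features (`snv_features` or matrix).
#' @param labels Evaluation labels (metadata labels when omitted).
#' @param eval_cohort Tag for the report.
#' @param outdir If non-`NULL`, the report is written there as
#'   `transfer_report.json`.
#' @return A `classifier_report`.
#' @export
run_transfer <- function(fit, x, labels = NULL, eval_cohort = "transfer",
                         outdir = NULL) {
  if (is.character(fit)) {
    path <- file.path(fit, "model.rds")
    if (!file.exists(path)) stopf("no model.rds under %s", fit)
    fit <- readRDS(path)
  }
  model <- if (inherits(fit, "snv_marker_fit")) fit$classifier else fit
  rep <- evaluate_classifier(model, x, labels, mode = "transfer",
                             eval_cohort = eval_cohort)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(auc = rep$auc, mode = rep$mode,
                              n_positive = rep$n_positive,
                              n_negative = rep$n_negative,
                              train_cohort = rep$train_cohort,
                              eval_cohort = rep$eval_cohort),
                         file.path(outdir, "transfer_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  rep
}
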