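#' Discovery workflow: cluster-labeled cells to an oriented signature set
#'
#' Chains pairwise differential expression, Ward module clustering of the
#' DEG union's per-cluster profile, and module orientation into a
#' [signature_set()] whose first modules are injury-induced (+1) and later
#' modules suppressed (-1). When `out_dir` is given, the DEG table (CSV),
#' the signatures (GMT) and the run configuration (YAML, including the
#' orientation contrast) are written there.
#'
#' @param x a `ClusterLabeledMatrix`.
#' @param k number of modules to cut (default 6).
#' @param method,fc_min,alpha forwarded to [pairwise_degs()].
#' @param contrast orientation contrast over cluster-profile columns,
#'   forwarded to [cluster_gene_modules()].
#' @param n_induced how many of the k modules get sign +1 (default
#'   `ceiling(k/2)`).
#' @param out_dir optional output directory.
#' @return List: `signatures` ([signature_set()]), `modules` (gene ->
#'   module factor), `degs` (the `DEGTable`).
#' @export
run_discovery <- function(x, k = 6, method = "wilcoxon", fc_min = 2,
                          alpha = 0.05, contrast = NULL,
                          n_induced = ceiling(k / 2), out_dir = NULL) {
  degs <- pairwise_degs(x, method = method, fc_min = fc_min, alpha = alpha)
  if (length(degs$genes) < k)
    stop("discovery stage [degs]: only ", length(degs$genes),
         " DEGs for k = ", k, " modules")
  prof <- cluster_means(x, genes = degs$genes)
  modules <- cluster_gene_modules(prof, k = k, contrast = contrast)
  genes <- split(names(modules), modules)
  signs <- rep(c(1, -1), c(n_induced, k - n_induced))
  sigs <- signature_set(genes, signs = signs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(degs$table, file.path(out_dir, "deg_table.csv"),
                     row.names = FALSE)
    write_gmt(sigs, file.path(out_dir, "signatures.gmt"))
    yaml::write_yaml(list(k = k, method = method, fc_min = fc_min,
                          alpha = alpha, n_induced = n_induced),
                     file.path(out_dir, "discovery_config.yaml"))
  }
  list(signatures = sigs, modules = modules, degs = degs)
}

#' Pick each patient's first sampled time point
#'
#' Earliest `timepoint_hours` per patient; exact ties are broken by sample
#' id. Control samples are dropped.
#'
#' @param metadata sample table with `sample_id`, `patient_id`,
#'   `timepoint_hours` and `group` columns.
#' @return Character vector of sample ids, one per patient.
#' @export
first_timepoint_samples <- function(metadata) {
  pt <- metadata[metadata$group == "patient", , drop = FALSE]
  if (nrow(pt) == 0) stop("no patient samples in metadata")
  pt <- pt[order(pt$patient_id, pt$timepoint_hours, pt$sample_id), ]
  pt$sample_id[!duplicated(pt$patient_id)]
}

#' Classification workflow: expression to subtypes, classifier and outcomes
#'
#' The application arm of the pipeline: extract each patient's first
#' sampled time point, compute cross-patient signature scores, cluster into
#' SG1/SG2, compute intrinsic scores and IDS, train the cross-validated
#' random-forest classifier on the intrinsic scores, and (when a survival
#' table is supplied) run the 28-day Kaplan-Meier / log-rank comparison and
#' the covariate-adjusted Cox model of recovery.
#'
#' @param expression log2-scale [expression_matrix()] (all samples).
#' @param sigs a [signature_set()].
#' @param metadata sample table (see [first_timepoint_samples()]).
#' @param survival optional per-patient survival table with `patient_id`,
#'   `time`, `event` and covariate columns.
#' @param folds,seed classifier cross-validation settings.
#' @param horizon Kaplan-Meier horizon in days.
#' @param out_dir optional directory for CSV/YAML outputs.
#' @return List of class `ClassificationRun`: `samples`, `scores`,
#'   `subtypes`, `intrinsic`, `ids`, `classifier`, and (if survival given)
#'   `km`, `logrank`, `cox`.
#' @export
run_classification <- function(expression, sigs, metadata, survival = NULL,
                               folds = 5, seed = 1, horizon = 28,
                               out_dir = NULL) {
  if (folds > length(unique(metadata$patient_id[metadata$group == "patient"])))
    stop("config error: more folds than patients")
  first <- first_timepoint_samples(metadata)
  m1 <- subset_expression(expression, samples = first)
  scores <- signature_scores(m1, sigs)
  subtypes <- cluster_subtypes(scores, signs = sigs$signs)
  intr <- intrinsic_scores(m1, sigs)
  clf <- train_subtype_classifier(intr, subtypes$labels, folds = folds,
                                  seed = seed)
  # map sample-level labels to patients
  pt_of <- metadata$patient_id[match(first, metadata$sample_id)]
  patient_label <- stats::setNames(as.character(subtypes$labels[first]), pt_of)

  out <- list(samples = first, scores = scores, subtypes = subtypes,
              intrinsic = intr, ids = intr$ids, classifier = clf,
              patient_label = patient_label)
  if (!is.null(survival)) {
    sv <- survival
    sv$subtype <- patient_label[sv$patient_id]
    sv <- sv[!is.na(sv$subtype), , drop = FALSE]
    out$km <- km_estimate(sv$time, sv$event, sv$subtype, horizon = horizon)
    out$logrank <- logrank_test(sv$time, sv$event, sv$subtype)
    covs <- intersect(c("subtype", "age", "sex", "severity_score",
                        "lactate_max_6h"), names(sv))
    out$cox <- cox_fit(sv$time, sv$event, sv[covs])
    out$survival <- sv
  } else {
    warning("no survival table supplied; outcome stage skipped")
  }
  class(out) <- "ClassificationRun"
  if (!is.null(out_dir)) .write_classification(out, out_dir, seed, folds)
  out
}

.write_classification <- function(run, out_dir, seed, folds) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(sample_id = rownames(run$scores),
                              unclass(run$scores),
                              subtype = as.character(run$subtypes$labels),
                              check.names = FALSE),
                   file.path(out_dir, "signature_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(sample_id = rownames(run$intrinsic$ic),
                              run$intrinsic$ic, IDS = run$ids,
                              check.names = FALSE),
                   file.path(out_dir, "intrinsic_scores.csv"),
                   row.names = FALSE)
  rep <- run$classifier$report
  yaml::write_yaml(list(seed = seed, folds = folds,
                        mean_error = rep$mean_error,
                        sd_error = rep$sd_error, auc = rep$auc),
                   file.path(out_dir, "classifier_report.yaml"))
  if (!is.null(run$cox))
    utils::write.csv(run$cox$table, file.path(out_dir, "cox_summary.csv"),
                     row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.ClassificationRun <- function(x, ...) {
  cat("ClassificationRun:", length(x$samples), "patients;",
      sprintf("CV error %.3f, AUC %.3f", x$classifier$report$mean_error,
              x$classifier$report$auc), "\n")
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank p = %.3g (SG1 vs SG2 recovery)\n", x$logrank$p))
  invisible(x)
}
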