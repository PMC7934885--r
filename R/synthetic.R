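#' Specification of a synthetic critical-illness cohort
#'
#' Defines the generative model used throughout the test suite: six disjoint
#' gene modules (three injury-induced, three suppressed) embedded in a
#' background transcriptome; two latent patient subtypes (SG1, SG2) that
#' differ in the magnitude of induction/suppression; exponential decay of the
#' injury response toward the healthy baseline over the sampling times; and
#' recovery/death times whose hazard depends on subtype.
#'
#' Defaults describe a severe-injury cohort sampled longitudinally on
#' microarray-like log2 data: a 1000-gene universe of which 129 genes form
#' the modules (sizes 25/25/25/25/21/8), SG1 shifted by 2.0 log2 units and
#' SG2 by 0.7 at time zero, per-gene noise SD 0.5, sampling at 12/24/96/168
#' hours with a 96-hour return-to-baseline half-life, SG2 recovering three
#' times faster than SG1, and in-hospital mortality of 8% (SG1) vs 1.5%
#' (SG2).
#'
#' @param n_patients number of injured patients.
#' @param n_controls number of healthy-control samples.
#' @param n_background_genes genes outside any module.
#' @param module_sizes six positive counts, genes per signature C1..C6.
#' @param subtype_fractions probabilities of SG1 and SG2; must sum to 1.
#' @param induction_effect named length-2 vector `c(SG1=, SG2=)`: log2 shift
#'   applied to induced modules at time zero; SG1 must exceed SG2.
#' @param suppression_effect as above for suppressed modules (magnitude of
#'   the downward shift).
#' @param noise_sd per-gene log2-scale Gaussian noise SD.
#' @param timepoints sampling times in hours after injury.
#' @param decay_halflife hours for the injury effect to halve.
#' @param hazard_ratio_recovery SG2-vs-SG1 recovery hazard ratio (>1 means
#'   SG2 recovers faster).
#' @param mortality_prob named length-2 vector of per-subtype in-hospital
#'   death probabilities.
#' @param confounding additive shift of the severity covariate in SG1
#'   patients (0 = covariates independent of subtype).
#' @param seed integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A validated list of class `CohortSpec`.
#' @export
cohort_spec <- function(n_patients = 200,
                        n_controls = 20,
                        n_background_genes = 871,
                        module_sizes = c(25, 25, 25, 25, 21, 8),
                        subtype_fractions = c(SG1 = 0.5, SG2 = 0.5),
                        induction_effect = c(SG1 = 2.0, SG2 = 0.7),
                        suppression_effect = c(SG1 = 2.0, SG2 = 0.7),
                        noise_sd = 0.5,
                        timepoints = c(12, 24, 96, 168),
                        decay_halflife = 96,
                        hazard_ratio_recovery = 3,
                        mortality_prob = c(SG1 = 0.08, SG2 = 0.015),
                        confounding = 0,
                        seed = 1L) {
  stopifnot(n_patients >= 1, n_controls >= 0, n_background_genes >= 1)
  if (length(module_sizes) != 6 || any(module_sizes < 1))
    stop("module_sizes must be six positive counts")
  if (abs(sum(subtype_fractions) - 1) > 1e-12)
    stop("subtype_fractions must sum to 1")
  if (any(subtype_fractions < 0)) stop("subtype_fractions must be >= 0")
  if (length(induction_effect) != 2 || length(suppression_effect) != 2)
    stop("effects must be length-2 (SG1, SG2)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(timepoints) < 1 || any(timepoints < 0))
    stop("timepoints must be non-negative hours")
  if (decay_halflife <= 0) stop("decay_halflife must be positive")
  if (hazard_ratio_recovery <= 0) stop("hazard_ratio_recovery must be positive")
  if (any(mortality_prob < 0 | mortality_prob > 1))
    stop("mortality_prob must be probabilities")
  spec <- list(n_patients = as.integer(n_patients),
               n_controls = as.integer(n_controls),
               n_background_genes = as.integer(n_background_genes),
               module_sizes = as.integer(module_sizes),
               subtype_fractions = subtype_fractions,
               induction_effect = induction_effect,
               suppression_effect = suppression_effect,
               noise_sd = noise_sd,
               timepoints = sort(timepoints),
               decay_halflife = decay_halflife,
               hazard_ratio_recovery = hazard_ratio_recovery,
               mortality_prob = mortality_prob,
               confounding = confounding,
               seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  spec
}

.module_genes <- function(spec) {
  sig_names <- paste0("C", 1:6)
  genes <- vector("list", 6)
  for (k in 1:6)
    genes[[k]] <- sprintf("%sG%03d", sig_names[k], seq_len(spec$module_sizes[k]))
  names(genes) <- sig_names
  genes
}

#' Generate a synthetic longitudinal cohort with known subtype truth
#'
#' Patient expression at time t is
#' `baseline + sign_k * effect[subtype] * 2^(-t / halflife) + noise`
#' for genes in module k, and `baseline + noise` elsewhere; controls are
#' drawn from the baseline alone. Recovery times are exponential with
#' subtype-dependent hazard; deaths occur with the configured per-subtype
#' probability and are recorded with event = 0 (censored for recovery) at
#' the hospital length of stay.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `SyntheticCohort` with elements
#'   `expression` (log2-scale [expression_matrix()], one column per
#'   patient-timepoint sample plus controls), `metadata` (one row per
#'   sample: sample/patient ids, timepoint, group, true subtype,
#'   covariates), `survival` (per-patient time in days, event flag, event
#'   type, covariates, true subtype), and `signatures` (ground-truth
#'   [signature_set()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  n_sig <- sum(spec$module_sizes)
  sig_genes <- .module_genes(spec)
  bg <- sprintf("BG%04d", seq_len(spec$n_background_genes))
  genes <- c(unlist(sig_genes, use.names = FALSE), bg)
  signs <- rep(c(1, 1, 1, -1, -1, -1), spec$module_sizes)

  baseline <- stats::rnorm(length(genes), mean = 8, sd = 1.5)
  names(baseline) <- genes

  n <- spec$n_patients
  subtype <- sample(c("SG1", "SG2"), n, replace = TRUE,
                    prob = spec$subtype_fractions)
  # guarantee both subtypes when both fractions are positive and n allows
  if (all(spec$subtype_fractions > 0) && n >= 2 &&
      length(unique(subtype)) == 1)
    subtype[1:2] <- c("SG1", "SG2")
  patient_id <- sprintf("P%04d", seq_len(n))

  age <- round(pmax(18, pmin(90, stats::rnorm(n, 45, 15))))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  severity <- pmax(1, round(stats::rnorm(n, 25, 8) +
                              spec$confounding * (subtype == "SG1")))
  lactate <- round(stats::rlnorm(n, meanlog = log(2.5), sdlog = 0.45), 2)

  tp <- spec$timepoints
  decay <- 2^(-tp / spec$decay_halflife)
  eff_by_subtype <- function(st) {
    ind <- spec$induction_effect[[st]]
    sup <- spec$suppression_effect[[st]]
    ifelse(signs > 0, ind, -sup)
  }
  eff <- list(SG1 = c(eff_by_subtype("SG1"), rep(0, length(bg))),
              SG2 = c(eff_by_subtype("SG2"), rep(0, length(bg))))

  # one column per patient-timepoint sample, then controls
  pidx <- rep(seq_len(n), each = length(tp))
  tidx <- rep(seq_along(tp), times = n)
  ng <- length(genes)
  effmat <- cbind(SG1 = eff$SG1, SG2 = eff$SG2)
  mu_pt <- baseline + effmat[, subtype[pidx], drop = FALSE] *
    rep(decay[tidx], each = ng)
  expr_pt <- mu_pt + matrix(stats::rnorm(ng * length(pidx), 0, spec$noise_sd),
                            nrow = ng)
  pt_ids <- sprintf("%s_T%03dh", patient_id[pidx], as.integer(tp[tidx]))

  nc <- spec$n_controls
  expr_hc <- baseline + matrix(stats::rnorm(ng * nc, 0, spec$noise_sd),
                               nrow = ng)
  hc_ids <- sprintf("HC%03d", seq_len(nc))
  expr <- cbind(expr_pt, expr_hc)
  dimnames(expr) <- list(genes, c(pt_ids, hc_ids))

  metadata <- rbind(
    data.frame(sample_id = pt_ids,
               patient_id = patient_id[pidx],
               timepoint_hours = tp[tidx],
               group = "patient",
               subtype_true = subtype[pidx],
               age = age[pidx], sex = sex[pidx],
               severity_score = severity[pidx],
               lactate_max_6h = lactate[pidx],
               stringsAsFactors = FALSE),
    data.frame(sample_id = hc_ids,
               patient_id = hc_ids,
               timepoint_hours = NA_real_,
               group = "control",
               subtype_true = NA_character_,
               age = round(stats::runif(nc, 20, 60)),
               sex = sample(c("F", "M"), nc, replace = TRUE),
               severity_score = 0,
               lactate_max_6h = round(stats::rlnorm(nc, log(1.2), 0.2), 2),
               stringsAsFactors = FALSE))
  rownames(metadata) <- NULL

  # survival: recovery hazard for SG1 gives a ~12-day median stay; SG2
  # recovers hazard_ratio_recovery times faster
  lambda1 <- log(2) / 12
  lambda <- ifelse(subtype == "SG1", lambda1,
                   lambda1 * spec$hazard_ratio_recovery)
  dead <- stats::runif(n) < spec$mortality_prob[subtype]
  t_recov <- stats::rexp(n, rate = lambda)
  t_death <- stats::rexp(n, rate = log(2) / 8)
  time <- ifelse(dead, t_death, t_recov)
  time <- pmax(1, ceiling(time))          # day-resolution annotation
  survival <- data.frame(patient_id = patient_id,
                         time = time,
                         event = as.integer(!dead),
                         event_type = ifelse(dead, "death", "recovery"),
                         age = age, sex = sex,
                         severity_score = severity,
                         lactate_max_6h = lactate,
                         subtype_true = subtype,
                         stringsAsFactors = FALSE)

  out <- list(expression = expression_matrix(expr, scale = "log2"),
              metadata = metadata,
              survival = survival,
              signatures = signature_set(sig_genes,
                                         signs = c(1, 1, 1, -1, -1, -1)),
              spec = spec)
  class(out) <- "SyntheticCohort"
  out
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf(paste0("SyntheticCohort: %d patients x %d timepoints + %d ",
                     "controls, %d genes (%d in modules)\n"),
              x$spec$n_patients, length(x$spec$timepoints),
              x$spec$n_controls, nrow(x$expression$values),
              sum(x$spec$module_sizes)))
  invisible(x)
}

#' Generate a cluster-labeled cell-by-gene count matrix
#'
#' Produces negative-binomial counts for `n_clusters` cell clusters over the
#' same gene universe as [generate_cohort()]. The first six clusters each
#' over-express one ground-truth module by `2^cluster_effect`; any further
#' clusters sit at baseline. Cluster means differ only in module genes, so
#' pairwise differential expression and module clustering have a known
#' truth.
#'
#' @param spec a [cohort_spec()].
#' @param cells_per_cluster cells per cluster (>= 3; rank tests are
#'   undefined below that).
#' @param n_clusters number of clusters (>= 2).
#' @param cluster_effect log2 shift of the focal module in its cluster.
#' @param dispersion negative-binomial size parameter.
#' @return A list of class `ClusterLabeledMatrix` with `expression`
#'   (counts-scale [expression_matrix()], cells as samples), `cluster`
#'   (factor per cell), and `truth` (gene to module map for module genes).
#' @export
generate_cell_matrix <- function(spec, cells_per_cluster = 100,
                                 n_clusters = 7, cluster_effect = 3,
                                 dispersion = 2) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (n_clusters < 2) stop("at least 2 clusters are required")
  if (cells_per_cluster < 3)
    stop("cells_per_cluster must be >= 3 (rank tests undefined below)")
  set.seed(spec$seed + 7919L)  # offset so cohort and cells are independent
  sig_genes <- .module_genes(spec)
  bg <- sprintf("BG%04d", seq_len(spec$n_background_genes))
  genes <- c(unlist(sig_genes, use.names = FALSE), bg)
  module_of <- rep(c(names(sig_genes), "background"),
                   c(spec$module_sizes, length(bg)))
  names(module_of) <- genes

  base_mu <- stats::rlnorm(length(genes), meanlog = 0, sdlog = 1)
  names(base_mu) <- genes

  n_cells <- n_clusters * cells_per_cluster
  cluster <- factor(rep(sprintf("K%d", seq_len(n_clusters)),
                        each = cells_per_cluster))
  counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                   dimnames = list(genes,
                                   sprintf("cell%05d", seq_len(n_cells))))
  for (k in seq_len(n_clusters)) {
    mu <- base_mu
    if (k <= 6) {
      focal <- sig_genes[[k]]
      mu[focal] <- mu[focal] * 2^cluster_effect
    }
    idx <- which(as.integer(cluster) == k)
    counts[, idx] <- stats::rnbinom(length(genes) * length(idx),
                                    mu = mu, size = dispersion)
  }
  out <- list(expression = expression_matrix(counts, scale = "counts"),
              cluster = cluster,
              truth = module_of[module_of != "background"])
  class(out) <- "ClusterLabeledMatrix"
  out
}

#' Write a synthetic cohort to disk in standard formats
#'
#' Expression as TSV, signatures as GMT, metadata and survival as CSV, and
#' the generator configuration (including the seed) as a YAML sidecar.
#'
#' @param cohort a `SyntheticCohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_gmt(cohort$signatures, file.path(dir, "signatures.gmt"))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$survival, file.path(dir, "survival.csv"),
                   row.names = FALSE)
  yaml::write_yaml(unclass(cohort$spec), file.path(dir, "cohort_spec.yaml"))
  invisible(dir)
}
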