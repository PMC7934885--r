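# Shared fixtures. Heavy per-seed pipeline runs are cached so that the
# subtype-recovery and end-to-end tests reuse the same cohorts.

make_expr <- function(v, scale = "log2") {
  if (is.null(dimnames(v)))
    dimnames(v) <- list(paste0("g", seq_len(nrow(v))),
                        paste0("s", seq_len(ncol(v))))
  expression_matrix(v, scale = scale)
}

# small six-signature set over 18 genes
small_sigs <- function() {
  signature_set(split(paste0("g", 1:18), rep(paste0("C", 1:6), each = 3)),
                signs = c(1, 1, 1, -1, -1, -1))
}

# reduced-size cell spec so DEG tests stay fast
cell_spec <- function(seed = 1, ...) {
  cohort_spec(n_background_genes = 150,
              module_sizes = c(8, 8, 8, 8, 6, 4), seed = seed, ...)
}

.pipeline_cache <- new.env(parent = emptyenv())

# one full application run on a default synthetic cohort for a given seed
pipeline_run <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  co <- generate_cohort(cohort_spec(seed = seed))
  run <- run_classification(co$expression, co$signatures, co$metadata,
                            co$survival, folds = 5, seed = seed)
  truth <- stats::setNames(co$survival$subtype_true, co$survival$patient_id)
  res <- list(cohort = co, run = run, truth = truth)
  .pipeline_cache[[key]] <- res
  res
}

ari <- function(a, b) {
  # adjusted Rand index from the pair-counting definition
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  np <- choose(sum(tab), 2)
  exp_ij <- si * sj / np
  (sij - exp_ij) / ((si + sj) / 2 - exp_ij)
}
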