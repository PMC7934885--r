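#' Cross-patient signature scores
#'
#' For every signature gene, expression is z-scored across samples (sample
#' SD, n-1 denominator); the score of a signature in a sample is the mean of
#' its member genes' z-scores. This normalization makes scores comparable
#' across genes within one cohort, but because the z-scoring runs across
#' patients it is cohort-relative: a patient's score depends on who else is
#' in the matrix. Use [intrinsic_scores()] for a patient-autonomous
#' quantity.
#'
#' Genes absent from the matrix are dropped and reported via the
#' `coverage` attribute; a signature with coverage below `min_coverage`
#' (or with no genes present at all) is an error. Zero-variance genes
#' contribute a z-score of 0.
#'
#' @param m an [expression_matrix()] with at least 2 samples.
#' @param sigs a [signature_set()].
#' @param min_coverage minimum fraction of a signature's genes that must be
#'   present in the matrix (default 0.5).
#' @return A samples x signatures numeric matrix of class `ScoreMatrix`
#'   with attributes `provenance = "cross_patient"`, `coverage` (fraction
#'   of member genes present per signature), and `signs`.
#' @examples
#' m <- expression_matrix(matrix(c(1, 3), 1, 2,
#'   dimnames = list("A", c("s1", "s2"))), scale = "log2")
#' ss <- signature_set(list(C1 = "A"), signs = 1)
#' signature_scores(m, ss)  # -1/sqrt(2), +1/sqrt(2)
#' @export
signature_scores <- function(m, sigs, min_coverage = 0.5) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(sigs, "SignatureSet"))
  if (ncol(m$values) < 2)
    stop("at least 2 samples are required to z-score across patients")
  v <- m$values
  cov <- vapply(sigs$genes, function(g) mean(g %in% rownames(v)), numeric(1))
  if (any(cov == 0))
    stop("no genes present for signature(s): ",
         paste(sigs$names[cov == 0], collapse = ", "))
  if (any(cov < min_coverage))
    stop("signature coverage below ", min_coverage, " for: ",
         paste(sprintf("%s (%.0f%%)", sigs$names[cov < min_coverage],
                       100 * cov[cov < min_coverage]), collapse = ", "))
  scores <- matrix(NA_real_, nrow = ncol(v), ncol = length(sigs$genes),
                   dimnames = list(colnames(v), sigs$names))
  for (nm in sigs$names) {
    g <- intersect(sigs$genes[[nm]], rownames(v))
    z <- .zscore_rows(v[g, , drop = FALSE])
    scores[, nm] <- colMeans(z)
  }
  structure(scores, class = c("ScoreMatrix", class(scores)),
            provenance = "cross_patient", coverage = cov,
            signs = sigs$signs)
}

# row-wise z-score with sample SD; constant rows map to 0
.zscore_rows <- function(v) {
  mu <- rowMeans(v)
  s <- apply(v, 1, stats::sd)
  z <- (v - mu) / s
  z[s == 0, ] <- 0
  z
}

#' Within-patient intrinsic signature scores and IDS
#'
#' For each patient independently: (a) take the log2 expression of the
#' signature genes, (b) z-score across those genes within the patient
#' (sample SD), (c) average the z-scores per signature. The resulting
#' IC1..IC6 depend only on the patient's own profile, so they transfer
#' across cohorts and platforms; by construction the gene-count-weighted sum
#' of a patient's IC values is zero. The Intrinsic Deviation Score (IDS) is
#' the signed sum of the IC values (see [ids()]).
#'
#' Patients whose signature-gene vector is constant have undefined z-scores;
#' they are excluded (all IC set to NA) and listed in `$excluded`.
#'
#' @param m an [expression_matrix()] on log2 scale.
#' @param sigs a [signature_set()].
#' @param min_coverage minimum per-signature gene coverage, as in
#'   [signature_scores()].
#' @return An object of class `IntrinsicScores`: list with `ic` (patients x
#'   signatures matrix), `ids` (named numeric), `signs`, `n_genes_used`
#'   (genes present per signature), and `excluded` (patient ids with
#'   constant profiles).
#' @export
intrinsic_scores <- function(m, sigs, min_coverage = 0.5) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(sigs, "SignatureSet"))
  if (m$scale != "log2")
    stop("intrinsic scores require log2-scale input; see log2_transform()")
  v <- m$values
  present <- lapply(sigs$genes, intersect, rownames(v))
  cov <- lengths(present) / lengths(sigs$genes)
  if (any(cov == 0))
    stop("no genes present for signature(s): ",
         paste(sigs$names[cov == 0], collapse = ", "))
  if (any(cov < min_coverage))
    stop("signature coverage below ", min_coverage, " for: ",
         paste(sigs$names[cov < min_coverage], collapse = ", "))
  all_genes <- unlist(present, use.names = FALSE)
  sub <- v[all_genes, , drop = FALSE]
  sig_of <- rep(sigs$names, lengths(present))

  mu <- colMeans(sub)
  s <- apply(sub, 2, stats::sd)
  excluded <- colnames(sub)[s == 0]
  ic <- matrix(NA_real_, nrow = ncol(sub), ncol = length(sigs$names),
               dimnames = list(colnames(sub), sigs$names))
  ok <- s > 0
  z <- sweep(sweep(sub[, ok, drop = FALSE], 2, mu[ok]), 2, s[ok], "/")
  for (nm in sigs$names)
    ic[ok, nm] <- colMeans(z[sig_of == nm, , drop = FALSE])
  out <- list(ic = ic,
              ids = .ids_from_matrix(ic, sigs$signs),
              signs = sigs$signs,
              n_genes_used = lengths(present),
              excluded = excluded)
  class(out) <- "IntrinsicScores"
  out
}

#' @export
print.IntrinsicScores <- function(x, ...) {
  cat(sprintf("IntrinsicScores: %d patients x %d signatures (%d excluded)\n",
              nrow(x$ic), ncol(x$ic), length(x$excluded)))
  invisible(x)
}

.ids_from_matrix <- function(ic, signs) {
  drop(ic %*% signs[colnames(ic)])
}

#' Intrinsic Deviation Score
#'
#' `IDS = sum_k s_k * IC_k` where `s_k` is +1 for injury-induced signatures
#' and -1 for suppressed signatures. A high IDS means the patient's myeloid
#' program deviates strongly from steady state (induced programs up,
#' steady-state programs down). With `normalize = "mean"` the sum is divided
#' by the number of signatures; this rescaling preserves all patient
#' orderings.
#'
#' @param ic an [intrinsic_scores()] result, or a patients x signatures
#'   matrix of IC values.
#' @param signs +1/-1 per signature; taken from `ic` when it is an
#'   `IntrinsicScores` object.
#' @param normalize `"sum"` (default) or `"mean"`.
#' @return Named numeric vector of per-patient IDS.
#' @export
ids <- function(ic, signs = NULL, normalize = c("sum", "mean")) {
  normalize <- match.arg(normalize)
  if (inherits(ic, "IntrinsicScores")) {
    if (is.null(signs)) signs <- ic$signs
    ic <- ic$ic
  }
  if (is.null(signs)) stop("'signs' required when 'ic' is a plain matrix")
  if (!all(signs %in% c(1, -1))) stop("signs must be +1 or -1")
  if (length(signs) != ncol(ic))
    stop("need one sign per signature column")
  if (is.null(names(signs))) names(signs) <- colnames(ic)
  out <- .ids_from_matrix(ic, signs)
  if (normalize == "mean") out <- out / ncol(ic)
  out
}
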