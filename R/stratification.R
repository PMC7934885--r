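#' Cluster patients into SG1/SG2 subtypes from signature scores
#'
#' Agglomerative Ward clustering (Euclidean distance, `ward.D2`) of patients
#' in the 6-dimensional signature-score space, cut into two groups. The
#' group whose mean signed score `sum_k s_k * score_k` is higher — i.e. the
#' group with stronger induced programs and weaker steady-state programs —
#' is labeled SG1; the other SG2. SG1 is the high-deviation, worse-prognosis
#' subtype.
#'
#' @param scores a samples x signatures `ScoreMatrix` (or plain matrix).
#' @param signs +1/-1 per signature; defaults to the `signs` attribute of
#'   `scores` when present.
#' @param k number of subtypes (default 2; exposed for sensitivity checks).
#' @return A list of class `SubtypeAssignment`: `labels` (named factor
#'   SG1/SG2), `hclust` (the dendrogram), `signed_means` (per-cluster mean
#'   signed score), `k`.
#' @export
cluster_subtypes <- function(scores, signs = NULL, k = 2) {
  x <- unclass(scores)
  if (is.null(signs)) signs <- attr(scores, "signs")
  if (is.null(signs))
    signs <- rep(c(1, -1), c(ceiling(ncol(x) / 2), floor(ncol(x) / 2)))
  if (nrow(x) < 2 * k) stop("too few patients to cut into ", k, " subtypes")
  d <- stats::dist(x)
  if (all(d == 0)) stop("all patients identical in score space; no structure")
  hc <- stats::hclust(d, method = "ward.D2")
  grp <- stats::cutree(hc, k = k)
  signed <- drop(x %*% signs)
  grp_mean <- tapply(signed, grp, mean)
  # order clusters by decreasing mean signed score: SG1 first
  ord <- order(grp_mean, decreasing = TRUE)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- factor(paste0("SG", relabel[grp]),
                   levels = paste0("SG", seq_len(k)))
  names(labels) <- rownames(x)
  structure(list(labels = labels, hclust = hc,
                 signed_means = grp_mean[ord], k = k),
            class = "SubtypeAssignment")
}

#' @export
print.SubtypeAssignment <- function(x, ...) {
  cat("SubtypeAssignment:", paste(sprintf("%s=%d", levels(x$labels),
                                          tabulate(x$labels)),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' PCA of the signature-score matrix
#'
#' Centered (optionally standardized) principal components of the samples x
#' signatures score matrix, with variance fractions and loadings, plus
#' identification of the "separation PC": the component whose loadings best
#' align with the induced/suppressed sign pattern, which is the axis along
#' which the SG subtypes separate.
#'
#' @param scores samples x signatures matrix.
#' @param signs +1/-1 per signature (defaults to the matrix attribute).
#' @param standardize scale columns to unit variance before PCA.
#' @return List with `x` (PC coordinates), `loadings`, `var_fraction`
#'   (sums to 1), and `separation_pc` (index of the sign-aligned PC).
#' @export
score_pca <- function(scores, signs = NULL, standardize = FALSE) {
  x <- unclass(scores)
  if (nrow(x) < 3) stop("at least 3 patients are required for PCA")
  if (is.null(signs)) signs <- attr(scores, "signs")
  if (is.null(signs))
    signs <- rep(c(1, -1), c(ceiling(ncol(x) / 2), floor(ncol(x) / 2)))
  p <- stats::prcomp(x, center = TRUE, scale. = standardize)
  vf <- p$sdev^2 / sum(p$sdev^2)
  # sign-pattern alignment: |correlation| of each PC's loadings with signs
  align <- abs(drop(crossprod(p$rotation, signs))) /
    sqrt(colSums(p$rotation^2) * sum(signs^2))
  list(x = p$x, loadings = p$rotation, var_fraction = vf,
       separation_pc = unname(which.max(align)))
}

#' Train the random-forest subtype classifier with cross-validation
#'
#' Fits a random forest on the six intrinsic signature scores to predict
#' SG1/SG2 membership, evaluated by stratified k-fold cross-validation:
#' per-fold misclassification error and the AUC of the pooled out-of-fold
#' SG1 probabilities. The final model is refit on the full data. Because
#' intrinsic scores are patient-autonomous, this classifier can be applied
#' to external cohorts without renormalization.
#'
#' @param ic an [intrinsic_scores()] result or a patients x 6 IC matrix.
#' @param labels factor of SG1/SG2 labels (e.g. from [cluster_subtypes()]),
#'   named by patient or aligned with the rows of `ic`.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed; folds and forests are deterministic given it.
#' @param ntree,mtry random-forest hyperparameters (500 trees, sqrt(p)).
#' @return A list of class `SubtypeClassifier`: `model` (final
#'   randomForest), `report` (per-fold errors, mean/SD error, AUC),
#'   `oof_prob` (out-of-fold SG1 probabilities), `fold_of`, `feature_names`.
#' @export
train_subtype_classifier <- function(ic, labels, folds = 5, seed = 1,
                                     ntree = 500, mtry = NULL) {
  X <- if (inherits(ic, "IntrinsicScores")) ic$ic else as.matrix(ic)
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  if (!is.null(names(labels)) && !is.null(rownames(X)))
    labels <- labels[rownames(X)]
  else
    labels <- labels[keep]
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2) stop("both subtype labels must be present")
  if (folds < 2) stop("folds must be >= 2")
  if (nrow(X) < folds) stop("more folds than patients")
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(X))))

  set.seed(seed)
  # stratified fold assignment: shuffle within class, deal round-robin
  fold_of <- integer(nrow(X))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  pos <- levels(y)[1]          # SG1 sorts first
  oof <- rep(NA_real_, nrow(X))
  fold_err <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    set.seed(seed + f)
    fit <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                      ntree = ntree, mtry = mtry)
    pr <- stats::predict(fit, X[!tr, , drop = FALSE], type = "prob")[, pos]
    oof[!tr] <- pr
    fold_err[f] <- mean((pr >= 0.5) != (y[!tr] == pos))
  }
  auc <- .auc(y == pos, oof)
  set.seed(seed)
  final <- randomForest::randomForest(X, y, ntree = ntree, mtry = mtry)
  names(oof) <- rownames(X)
  structure(list(model = final,
                 report = list(fold_error = fold_err,
                               mean_error = mean(fold_err),
                               sd_error = stats::sd(fold_err),
                               auc = auc, folds = folds, seed = seed),
                 oof_prob = oof, fold_of = fold_of,
                 positive = pos, feature_names = colnames(X)),
            class = "SubtypeClassifier")
}

#' @export
print.SubtypeClassifier <- function(x, ...) {
  cat(sprintf("SubtypeClassifier: %d-fold CV error %.3f +/- %.3f, AUC %.3f\n",
              x$report$folds, x$report$mean_error, x$report$sd_error,
              x$report$auc))
  invisible(x)
}

.auc <- function(is_pos, prob) {
  ok <- !is.na(prob)
  r <- pROC::roc(response = factor(ifelse(is_pos[ok], "pos", "neg"),
                                   levels = c("neg", "pos")),
                 predictor = prob[ok], direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Predict subtype membership for new patients
#'
#' @param object a trained `SubtypeClassifier`.
#' @param ic_new an [intrinsic_scores()] result or IC matrix whose columns
#'   match the classifier's feature names.
#' @param ... unused.
#' @return Data frame with `prob_SG1` and hard `label` at the 0.5 threshold.
#' @export
predict_subtype <- function(object, ic_new, ...) {
  stopifnot(inherits(object, "SubtypeClassifier"))
  X <- if (inherits(ic_new, "IntrinsicScores")) ic_new$ic else as.matrix(ic_new)
  if (!all(object$feature_names %in% colnames(X)))
    stop("feature-name mismatch: classifier expects ",
         paste(object$feature_names, collapse = ", "))
  X <- X[, object$feature_names, drop = FALSE]
  keep <- stats::complete.cases(X)
  prob <- rep(NA_real_, nrow(X))
  if (any(keep))
    prob[keep] <- stats::predict(object$model, X[keep, , drop = FALSE],
                                 type = "prob")[, object$positive]
  data.frame(patient = rownames(X) %||% seq_len(nrow(X)),
             prob_SG1 = prob,
             label = ifelse(prob >= 0.5, object$positive,
                            setdiff(levels(object$model$y),
                                    object$positive)[1]),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
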