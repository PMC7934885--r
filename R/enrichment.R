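#' Overlap counts between two gene sets in a universe
#'
#' @param set1,set2 character vectors of gene ids.
#' @param universe character vector defining the gene universe N (genes
#'   outside the universe are ignored).
#' @return List of class `OverlapCounts`: `a` shared genes, `b` only in
#'   set 2, `c` only in set 1, `N` universe size, `overlap` the shared gene
#'   ids.
#' @export
overlap_counts <- function(set1, set2, universe) {
  universe <- unique(universe)
  s1 <- intersect(unique(set1), universe)
  s2 <- intersect(unique(set2), universe)
  shared <- intersect(s1, s2)
  out <- list(a = length(shared), b = length(setdiff(s2, s1)),
              c = length(setdiff(s1, s2)), N = length(universe),
              overlap = shared)
  class(out) <- "OverlapCounts"
  out
}

.check_counts <- function(counts) {
  with(counts, {
    if (any(c(a, b, c) < 0) || N <= 0) stop("invalid overlap counts")
    if (a + b + c > N) stop("overlap counts exceed universe size")
    if (a + b == 0 || a + c == 0) stop("empty gene set")
  })
}

#' Fold enrichment of a gene-set overlap
#'
#' `FE = a * N / ((a + b) * (a + c))`: the observed overlap divided by the
#' overlap expected if the two sets were drawn independently from the
#' universe. Symmetric in the two sets; FE = 1 means no enrichment.
#'
#' @param counts an [overlap_counts()] object (or list with a, b, c, N).
#' @return Numeric fold enrichment.
#' @examples
#' fold_enrichment(list(a = 10, b = 0, c = 0, N = 100))  # 10
#' @export
fold_enrichment <- function(counts) {
  .check_counts(counts)
  with(counts, a * N / ((a + b) * (a + c)))
}

#' Upper-tail hypergeometric P for a gene-set overlap
#'
#' P(X >= a) where X counts the overlap of a random size-(a+b) draw from a
#' universe of N genes containing a+c marked genes.
#'
#' @param counts an [overlap_counts()] object.
#' @return P value in (0, 1].
#' @export
hypergeom_p <- function(counts) {
  .check_counts(counts)
  with(counts, {
    if (a > min(a + b, a + c)) stop("impossible overlap configuration")
    stats::phyper(a - 1, a + c, N - (a + c), a + b, lower.tail = FALSE)
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control, monotone and capped at 1.
#'
#' @param p numeric vector of raw P values in \[0, 1\].
#' @return Adjusted P values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Enrichment of gene-set pairs with FE, hypergeometric P and BH adjustment
#'
#' Convenience wrapper testing every pair (one set from `sets1`, one from
#' `sets2`), with report-level filters on FE and overlap size as used when
#' relating modules to regulons.
#'
#' @param sets1,sets2 named lists of gene-id vectors (a [signature_set()]
#'   also works via its `genes` element).
#' @param universe gene universe (e.g. genes expressed in >= 0.5% of cells).
#' @param fe_min,min_overlap report filters (defaults keep everything).
#' @return Data frame: set1, set2, a, FE, p, p_adj, pass.
#' @export
set_enrichment <- function(sets1, sets2, universe, fe_min = 0,
                           min_overlap = 0) {
  if (inherits(sets1, "SignatureSet")) sets1 <- sets1$genes
  if (inherits(sets2, "SignatureSet")) sets2 <- sets2$genes
  grid <- expand.grid(s1 = names(sets1), s2 = names(sets2),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cnt <- overlap_counts(sets1[[grid$s1[i]]], sets2[[grid$s2[i]]], universe)
    data.frame(set1 = grid$s1[i], set2 = grid$s2[i], a = cnt$a,
               FE = fold_enrichment(cnt), p = hypergeom_p(cnt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$pass <- out$p_adj < 0.05 & out$FE >= fe_min & out$a >= min_overlap
  out
}

#' Cluster-by-time enrichment: odds ratios and chi-square tests
#'
#' For each (cluster, time) combination, a 2x2 table of cell counts
#' (in-cluster/in-time vs the rest) gives an odds ratio (Haldane-Anscombe
#' 0.5 correction when any cell is zero) and a two-sided Pearson chi-square
#' P (no continuity correction); P values are BH-adjusted across all
#' combinations. Each cluster is then labeled with its enrichment time via
#' [label_pan()]: the time of maximal OR, or "pan" when no OR exceeds the
#' threshold.
#'
#' @param cluster,time factors (or vectors), one entry per cell.
#' @param pan_threshold highest-OR cutoff for the "pan" call (default 2.5).
#' @return List with `table` (cluster, time, or, p, p_adj) and `call`
#'   (named character: per-cluster enrichment label).
#' @export
cluster_time_enrichment <- function(cluster, time, pan_threshold = 2.5) {
  cluster <- factor(cluster); time <- factor(time)
  if (length(cluster) != length(time) || length(cluster) == 0)
    stop("cluster and time must be equal-length, non-empty")
  if (nlevels(cluster) < 2 || nlevels(time) < 2)
    stop("need >= 2 clusters and >= 2 time labels")
  tot <- length(cluster)
  rows <- list()
  for (cl in levels(cluster)) for (tm in levels(time)) {
    n11 <- sum(cluster == cl & time == tm)
    n10 <- sum(cluster == cl) - n11
    n01 <- sum(time == tm) - n11
    n00 <- tot - n11 - n10 - n01
    tab <- matrix(c(n11, n10, n01, n00), 2)
    or <- if (any(tab == 0))
      ((n11 + 0.5) * (n00 + 0.5)) / ((n10 + 0.5) * (n01 + 0.5))
    else (n11 * n00) / (n10 * n01)
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    rows[[length(rows) + 1L]] <-
      data.frame(cluster = cl, time = tm, or = or, p = p,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  call <- vapply(levels(cluster), function(cl) {
    ors <- out$or[out$cluster == cl]
    names(ors) <- out$time[out$cluster == cl]
    label_pan(ors, threshold = pan_threshold)
  }, character(1))
  list(table = out, call = call)
}

#' Label a cluster by its enrichment time, or "pan"
#'
#' A cluster distributed evenly along the time series (highest OR <=
#' threshold) is labeled "pan"; otherwise it takes the label of the time
#' point with maximal OR (earliest wins on an exact tie).
#'
#' @param or_by_time named numeric vector: one odds ratio per time label,
#'   in time order.
#' @param threshold the pan cutoff (default 2.5).
#' @return Character label.
#' @examples
#' label_pan(c(`4h` = 1.1, `24h` = 0.9, `72h` = 1.3, control = 1.0))  # "pan"
#' @export
label_pan <- function(or_by_time, threshold = 2.5) {
  if (length(or_by_time) == 0) stop("empty OR vector")
  if (is.null(names(or_by_time)))
    names(or_by_time) <- as.character(seq_along(or_by_time))
  if (max(or_by_time) <= threshold) return("pan")
  names(or_by_time)[which.max(or_by_time)]
}
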