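#' Pairwise differential expression between cell clusters
#'
#' For every unordered pair of clusters, each gene is tested by either a
#' Wilcoxon rank-sum test on log-normalized expression (the convention for
#' droplet scRNA-seq marker detection) or a logistic regression of cluster
#' membership on expression with an optional batch covariate, using a
#' likelihood-ratio test. P values are Bonferroni-adjusted over genes within
#' each pair. A gene is called a DEG if it passes `adj P < alpha` and
#' `|FC| >= fc_min` in at least one pair. Fold change is computed on
#' de-logged per-cluster means with a 0.01 pseudocount.
#'
#' Clusters with fewer than 3 cells are dropped with a warning; constant
#' genes get P = 1 by convention.
#'
#' @param x a `ClusterLabeledMatrix` (see [generate_cell_matrix()]) or a
#'   list with `expression` (an [expression_matrix()], cells as samples)
#'   and `cluster` (factor per cell), optionally `batch`.
#' @param method `"wilcoxon"` or `"logistic"`.
#' @param fc_min minimum fold change (linear scale, default 2).
#' @param alpha adjusted-P cutoff (default 0.05).
#' @return A list of class `DEGTable`: `table` (gene, pair, log2 fold
#'   change, p, p_adj, direction, pass) and `genes` (union of passing
#'   genes).
#' @export
pairwise_degs <- function(x, method = c("wilcoxon", "logistic"),
                          fc_min = 2, alpha = 0.05) {
  method <- match.arg(method)
  m <- x$expression
  stopifnot(inherits(m, "ExpressionMatrix"))
  cluster <- factor(x$cluster)
  batch <- x$batch
  if (length(cluster) != ncol(m$values))
    stop("one cluster label per cell is required")

  sizes <- table(cluster)
  small <- names(sizes)[sizes < 3]
  if (length(sizes) - length(small) < 2)
    stop("at least 2 clusters with >= 3 cells are required")
  if (length(small)) {
    warning("excluding cluster(s) with <3 cells: ",
            paste(small, collapse = ", "))
    keep <- !(cluster %in% small)
    m <- subset_expression(m, samples = which(keep))
    cluster <- droplevels(cluster[keep])
    if (!is.null(batch)) batch <- batch[keep]
  }

  ln <- .lognorm(m)              # log2-normalized expression
  lev <- levels(cluster)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  res <- vector("list", length(pairs))
  for (pi in seq_along(pairs)) {
    p2 <- pairs[[pi]]
    ia <- which(cluster == p2[1]); ib <- which(cluster == p2[2])
    va <- ln[, ia, drop = FALSE]; vb <- ln[, ib, drop = FALSE]
    mu_a <- rowMeans(2^va - 1); mu_b <- rowMeans(2^vb - 1)
    l2fc <- log2((mu_a + 0.01) / (mu_b + 0.01))
    pv <- vapply(seq_len(nrow(ln)), function(g) {
      xa <- va[g, ]; xb <- vb[g, ]
      if (stats::sd(c(xa, xb)) == 0) return(1)
      if (method == "wilcoxon") {
        # ties are ubiquitous in count data; the tie-corrected normal
        # approximation is used silently in that case
        suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
      } else {
        yy <- c(rep(1L, length(xa)), rep(0L, length(xb)))
        ex <- c(xa, xb)
        if (is.null(batch)) {
          f1 <- stats::glm(yy ~ ex, family = stats::binomial())
          f0 <- stats::glm(yy ~ 1, family = stats::binomial())
        } else {
          bb <- factor(batch[c(ia, ib)])
          if (nlevels(bb) > 1) {
            f1 <- stats::glm(yy ~ ex + bb, family = stats::binomial())
            f0 <- stats::glm(yy ~ bb, family = stats::binomial())
          } else {
            f1 <- stats::glm(yy ~ ex, family = stats::binomial())
            f0 <- stats::glm(yy ~ 1, family = stats::binomial())
          }
        }
        stats::pchisq(f0$deviance - f1$deviance,
                      df = f0$df.residual - f1$df.residual,
                      lower.tail = FALSE)
      }
    }, numeric(1))
    res[[pi]] <- data.frame(gene = rownames(ln),
                            cluster1 = p2[1], cluster2 = p2[2],
                            log2fc = l2fc, p = pv,
                            p_adj = stats::p.adjust(pv, "bonferroni"),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, res)
  tab$direction <- ifelse(tab$log2fc >= 0, "up", "down")
  tab$pass <- tab$p_adj < alpha & abs(tab$log2fc) >= log2(fc_min)
  structure(list(table = tab, genes = sort(unique(tab$gene[tab$pass]))),
            class = "DEGTable")
}

# depth-normalize to 10k per cell and log2(x+1); log2 data passed through
.lognorm <- function(m) {
  if (m$scale == "log2") return(m$values)
  v <- m$values
  depth <- colSums(v)
  depth[depth == 0] <- 1
  log2(sweep(v, 2, depth, "/") * 1e4 + 1)
}

#' Per-cluster mean expression profile
#'
#' Helper building the genes x clusters profile matrix that
#' [cluster_gene_modules()] consumes, on log-normalized scale.
#'
#' @param x a `ClusterLabeledMatrix`.
#' @param genes optional subset of genes (e.g. the DEG union).
#' @return genes x clusters matrix of mean log-normalized expression.
#' @export
cluster_means <- function(x, genes = NULL) {
  ln <- .lognorm(x$expression)
  if (!is.null(genes)) ln <- ln[genes, , drop = FALSE]
  cl <- factor(x$cluster)
  out <- vapply(levels(cl),
                function(k) rowMeans(ln[, cl == k, drop = FALSE]),
                numeric(nrow(ln)))
  rownames(out) <- rownames(ln)
  out
}

#' Cluster genes into modules by Ward hierarchical clustering
#'
#' Rows (genes) of the per-cluster (or per-pseudotime-bin) mean-expression
#' profile are z-scored, clustered with Ward linkage on Euclidean distance,
#' and the tree is cut into `k` modules. Modules are then relabeled C1..Ck
#' in decreasing order of their mean profile contrast, so injury-induced
#' modules come first; the default contrast compares the first profile
#' column against the last (early-vs-control when columns are ordered that
#' way). Genes are sorted lexicographically first, making the result
#' invariant to input order.
#'
#' @param profile genes x conditions numeric matrix (e.g. [cluster_means()]).
#' @param k number of modules (2 <= k <= number of genes).
#' @param contrast numeric weights over profile columns used to orient the
#'   module numbering; default `+1` on the first column, `-1` on the last.
#' @return Named factor mapping gene to module label `C1..Ck`.
#' @export
cluster_gene_modules <- function(profile, k, contrast = NULL) {
  profile <- as.matrix(profile)
  if (k > nrow(profile)) stop("k exceeds the number of genes")
  if (k < 1) stop("k must be >= 1")
  profile <- profile[order(rownames(profile)), , drop = FALSE]
  z <- .zscore_rows(profile)
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  grp <- stats::cutree(hc, k = k)
  if (is.null(contrast)) {
    contrast <- numeric(ncol(profile))
    contrast[1] <- 1
    contrast[length(contrast)] <- -1
  }
  orient <- drop(z %*% contrast)
  grp_score <- tapply(orient, grp, mean)
  ord <- order(grp_score, decreasing = TRUE)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  out <- factor(paste0("C", relabel[grp]), levels = paste0("C", seq_len(k)))
  names(out) <- rownames(profile)
  out
}

#' Genes associated with a principal-component coordinate
#'
#' Pearson correlation of each gene's (scaled) expression with a PC
#' coordinate across cells/samples, Benjamini-Hochberg adjustment, and the
#' standard gating: adjusted P <= alpha and |r| >= r_min. Zero-variance
#' genes are excluded and counted.
#'
#' @param m an [expression_matrix()] (cells/samples as columns).
#' @param pc_coordinates numeric, one coordinate per column of `m`.
#' @param alpha adjusted-P cutoff (default 0.05).
#' @param r_min minimum absolute correlation (default 0.3).
#' @return List with `selected` (gene, r, p, p_adj, direction for passing
#'   genes), `table` (all testable genes) and `n_zero_variance`.
#' @export
pc_associated_genes <- function(m, pc_coordinates, alpha = 0.05,
                                r_min = 0.3) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  if (length(pc_coordinates) != ncol(v))
    stop("need one PC coordinate per sample")
  s <- apply(v, 1, stats::sd)
  nzv <- sum(s == 0)
  v <- v[s > 0, , drop = FALSE]
  n <- ncol(v)
  if (n < 3) stop("at least 3 samples are required")
  r <- drop(stats::cor(t(v), pc_coordinates))
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  tab <- data.frame(gene = rownames(v), r = r, p = p,
                    p_adj = stats::p.adjust(p, "BH"),
                    direction = ifelse(r >= 0, "pos", "neg"),
                    stringsAsFactors = FALSE)
  sel <- tab[tab$p_adj <= alpha & abs(tab$r) >= r_min, , drop = FALSE]
  list(selected = sel[order(-abs(sel$r)), ], table = tab,
       n_zero_variance = nzv)
}
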