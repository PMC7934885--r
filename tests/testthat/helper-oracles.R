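# Independent reference implementations used as oracles. These deliberately
# avoid the code paths they check.

# BH step-up, written from the definition
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  sp <- p[o]
  q <- rev(cummin(rev(sp * n / seq_len(n))))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# upper-tail hypergeometric P by explicit combinatorial summation
hyper_reference <- function(a, m1, m2, N) {
  js <- seq(a, min(m1, m2))
  sum(choose(m1, js) * choose(N - m1, m2 - js)) / choose(N, m2)
}

# upper-tail hypergeometric P by brute-force enumeration of every draw
hyper_enumerate <- function(a, m1, m2, N) {
  set1 <- seq_len(m1)
  draws <- utils::combn(N, m2)
  hits <- apply(draws, 2, function(d) sum(d %in% set1) >= a)
  mean(hits)
}

# two-sided exact rank-sum p by enumeration of all group assignments
wilcox_enumerate <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# product-limit estimator written from the definition (one group)
km_reference <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    d <- sum(time == ut[i] & event == 1)
    n <- sum(time >= ut[i])
    s <- s * (1 - d / n)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# Cox partial log-likelihood for a single covariate, no ties (Breslow form,
# which equals Efron without ties); maximized on a grid
cox_grid_mle <- function(time, event, x, grid = seq(-4, 4, by = 5e-4)) {
  ll <- vapply(grid, function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }, numeric(1))
  grid[which.max(ll)]
}

auc_rank <- function(is_pos, score) {
  # Mann-Whitney form of the AUC, independent of pROC
  r <- rank(score)
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
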