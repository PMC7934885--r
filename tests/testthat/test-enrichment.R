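test_that("fold enrichment matches the observed/expected definition", {
  expect_equal(fold_enrichment(list(a = 10, b = 0, c = 0, N = 100)), 10)
  # expectation under independence: (a+b)(a+c)/N = 1 here, so FE = a/1
  expect_equal(fold_enrichment(list(a = 5, b = 5, c = 5, N = 100)), 5)
  # sets covering the whole universe cannot be enriched
  expect_equal(fold_enrichment(list(a = 50, b = 0, c = 0, N = 50)), 1)
  expect_error(fold_enrichment(list(a = 0, b = 0, c = 0, N = 10)), "empty")
  # symmetry in the two sets (b and c swap)
  expect_equal(fold_enrichment(list(a = 4, b = 7, c = 2, N = 60)),
               fold_enrichment(list(a = 4, b = 2, c = 7, N = 60)))
})

test_that("random sets have mean fold enrichment 1", {
  set.seed(10)
  N <- 200
  fe <- replicate(2000, {
    s1 <- sample(N, 20); s2 <- sample(N, 30)
    fold_enrichment(overlap_counts(s1, s2, seq_len(N)))
  })
  expect_equal(mean(fe), 1, tolerance = 0.05)
})

test_that("hypergeometric P matches enumeration for every N <= 12 configuration", {
  for (N in c(5, 8, 12)) {
    for (m1 in 1:N) for (m2 in 1:N) {
      lo <- max(0, m1 + m2 - N)
      for (a in lo:min(m1, m2)) {
        cnt <- list(a = a, b = m2 - a, c = m1 - a, N = N)
        expect_equal(hypergeom_p(cnt), hyper_reference(a, m1, m2, N),
                     tolerance = 1e-12,
                     info = sprintf("N=%d m1=%d m2=%d a=%d", N, m1, m2, a))
      }
    }
  }
  # and against literal draw-by-draw enumeration on a smaller universe
  for (N in c(6, 9)) {
    for (m1 in c(2, 4)) for (m2 in c(3, 5)) {
      for (a in max(0, m1 + m2 - N):min(m1, m2)) {
        cnt <- list(a = a, b = m2 - a, c = m1 - a, N = N)
        expect_equal(hypergeom_p(cnt), hyper_enumerate(a, m1, m2, N),
                     tolerance = 1e-12)
      }
    }
  }
  # worked case: perfect overlap of two 5-sets in a 10-universe
  expect_equal(hypergeom_p(list(a = 5, b = 0, c = 0, N = 10)), 1 / 252,
               tolerance = 1e-15)
  expect_equal(hypergeom_p(list(a = 0, b = 5, c = 5, N = 10)), 1)
  expect_error(hypergeom_p(list(a = 6, b = 0, c = 0, N = 5)), "exceed")
})

test_that("BH adjustment matches the step-up reference and is monotone", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_reference(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # rank-preserving
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("cluster-by-time enrichment: OR, Haldane correction and pan calls", {
  # direct 2x2 check: cells (20,10,10,20) => OR 4
  cl <- rep(c("A", "B"), c(30, 30))
  tm <- c(rep(c("t1", "t2"), c(20, 10)), rep(c("t1", "t2"), c(10, 20)))
  res <- cluster_time_enrichment(cl, tm)
  expect_equal(res$table$or[res$table$cluster == "A" &
                              res$table$time == "t1"], 4)
  # chi-square p agrees with stats::chisq.test on the same table
  p_ref <- chisq.test(matrix(c(20, 10, 10, 20), 2), correct = FALSE)$p.value
  expect_equal(res$table$p[res$table$cluster == "A" &
                             res$table$time == "t1"], p_ref)

  # cluster confined to one time point: corrected OR finite and maximal
  cl2 <- rep(c("A", "B"), c(10, 90))
  tm2 <- c(rep("t1", 10), rep(c("t1", "t2", "t3"), 30))
  res2 <- cluster_time_enrichment(cl2, tm2)
  orA <- res2$table$or[res2$table$cluster == "A"]
  expect_true(all(is.finite(orA)))
  expect_equal(res2$call[["A"]], "t1")
  expect_equal(res2$table$time[res2$table$cluster == "A"][which.max(orA)],
               "t1")
})

test_that("pan rule follows the highest-OR threshold", {
  expect_equal(label_pan(c(`4h` = 1.1, `24h` = 0.9, `72h` = 1.3,
                           control = 1.0)), "pan")
  expect_equal(label_pan(c(`4h` = 4, `24h` = 1, `72h` = 0.5,
                           control = 0.2)), "4h")
  expect_equal(label_pan(c(a = 3, b = 3, c = 1)), "a")  # earliest tie wins
  expect_equal(label_pan(c(a = 2.5, b = 2.5)), "pan")   # boundary inclusive
  expect_error(label_pan(numeric(0)), "empty")
})

test_that("independent labels give near-uniform chi-square significance", {
  set.seed(12)
  n <- 5000
  cl <- sample(paste0("K", 1:5), n, replace = TRUE)
  tm <- sample(paste0("t", 1:4), n, replace = TRUE)
  res <- cluster_time_enrichment(cl, tm)
  # raw p approximately uniform: significant fraction near alpha
  expect_lt(mean(res$table$p < 0.05), 0.25)
  expect_true(all(res$table$p_adj >= res$table$p))
})

test_that("set_enrichment applies the report-level FE/overlap filters", {
  universe <- paste0("g", 1:100)
  sets1 <- list(M1 = paste0("g", 1:20))
  sets2 <- list(R1 = paste0("g", 1:15),          # strong overlap
                R2 = paste0("g", 81:100))        # disjoint
  res <- set_enrichment(sets1, sets2, universe, fe_min = 2, min_overlap = 5)
  expect_true(res$pass[res$set2 == "R1"])
  expect_false(res$pass[res$set2 == "R2"])
  expect_equal(res$a[res$set2 == "R1"], 15)
})
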