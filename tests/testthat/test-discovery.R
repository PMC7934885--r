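test_that("rank-sum DEG testing matches exact enumeration at small n", {
  set.seed(20)
  for (i in 1:10) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    vals <- sample(1000, nx + ny)               # distinct values, no ties
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    expect_equal(wilcox.test(x, y)$p.value, wilcox_enumerate(x, y),
                 tolerance = 1e-12)
  }
})

test_that("pairwise DEGs detect a planted fold change with both tests", {
  sp <- cohort_spec(n_background_genes = 40,
                    module_sizes = c(2, 2, 2, 2, 1, 1), seed = 21)
  set.seed(21)
  mu <- rlnorm(50, 0, 1)
  counts_a <- matrix(rnbinom(50 * 500, mu = mu, size = 2), 50)
  mu_b <- mu; mu_b[7] <- mu_b[7] * 8            # one 8-fold gene
  counts_b <- matrix(rnbinom(50 * 500, mu = mu_b, size = 2), 50)
  v <- cbind(counts_a, counts_b)
  dimnames(v) <- list(paste0("g", 1:50), paste0("c", 1:1000))
  x <- list(expression = expression_matrix(v, "counts"),
            cluster = rep(c("A", "B"), each = 500))
  for (meth in c("wilcoxon", "logistic")) {
    deg <- pairwise_degs(x, method = meth)
    expect_true("g7" %in% deg$genes, info = meth)
    tab7 <- deg$table[deg$table$gene == "g7", ]
    expect_lt(tab7$log2fc, 0)                  # higher in cluster B
    expect_equal(tab7$direction, "down")
  }
})

test_that("identical clusters yield at most alpha-level false positives", {
  set.seed(22)
  fp <- replicate(25, {
    mu <- rlnorm(60, 0, 1)
    v <- matrix(rnbinom(60 * 60, mu = mu, size = 2), 60)
    dimnames(v) <- list(paste0("g", 1:60), paste0("c", 1:60))
    x <- list(expression = expression_matrix(v, "counts"),
              cluster = rep(c("A", "B"), each = 30))  # same population
    length(pairwise_degs(x)$genes)
  })
  # Bonferroni at alpha = 0.05 over 60 genes: expected false calls << 1
  expect_lt(mean(fp), 0.25)
})

test_that("DEG guards: degenerate clusters, small clusters, constant genes", {
  v <- matrix(c(1, 2), 1, 2, dimnames = list("g1", c("c1", "c2")))
  x <- list(expression = expression_matrix(v, "counts"),
            cluster = c("A", "B"))
  expect_error(suppressWarnings(pairwise_degs(x)), "2 clusters")

  set.seed(23)
  v2 <- matrix(rpois(20 * 23, 5), 20,
               dimnames = list(paste0("g", 1:20), paste0("c", 1:23)))
  v2[1, ] <- 0                                   # constant gene
  x2 <- list(expression = expression_matrix(v2, "counts"),
             cluster = rep(c("A", "B", "C"), c(10, 11, 2)))
  expect_warning(deg <- pairwise_degs(x2), "C")
  expect_true(all(deg$table$p[deg$table$gene == "g1"] == 1))
  # symmetry: A-vs-B fold change is minus B-vs-A, p unchanged
  x3 <- x2; x3$cluster <- rep(c("B", "A", "C"), c(10, 11, 2))
  deg3 <- suppressWarnings(pairwise_degs(x3))
  expect_equal(deg$table$log2fc, -deg3$table$log2fc, tolerance = 1e-12)
  expect_equal(deg$table$p, deg3$table$p, tolerance = 1e-12)
})

test_that("module clustering recovers separable blocks and honors k", {
  # two anti-correlated blocks
  prof <- rbind(matrix(rep(c(2, 0, 1), each = 6), 6, byrow = FALSE),
                matrix(rep(c(0, 2, 1), each = 6), 6, byrow = FALSE))
  prof <- prof + matrix(rnorm(36, 0, 0.01), 12)
  rownames(prof) <- sprintf("g%02d", 1:12)
  mods <- cluster_gene_modules(prof, k = 2)
  expect_equal(length(unique(mods[1:6])), 1)
  expect_equal(length(unique(mods[7:12])), 1)
  expect_false(mods[[1]] == mods[[7]])
  # block high in column 1 is labeled C1 by the default contrast
  expect_equal(as.character(mods[[1]]), "C1")

  expect_error(cluster_gene_modules(prof, k = 13), "exceeds")
  singletons <- cluster_gene_modules(prof, k = 12)
  expect_equal(nlevels(droplevels(singletons)), 12)

  # invariant to gene input order
  shuf <- sample(nrow(prof))
  mods2 <- cluster_gene_modules(prof[shuf, ], k = 2)
  expect_identical(mods2[names(mods)], mods)
})

test_that("discovery workflow recovers planted modules from cells", {
  for (s in c(31, 32, 33)) {
    cm <- generate_cell_matrix(cell_spec(seed = s), cells_per_cluster = 40)
    disc <- run_discovery(cm, k = 6)
    found <- disc$modules[names(cm$truth)[names(cm$truth) %in%
                                            names(disc$modules)]]
    # most planted genes found as DEGs, and module structure matches truth
    expect_gt(length(found) / length(cm$truth), 0.8)
    expect_gte(ari(as.character(found), cm$truth[names(found)]), 0.9)
    expect_s3_class(disc$signatures, "SignatureSet")
    expect_equal(sum(disc$signatures$signs == 1), 3)
  }
})

test_that("PC-associated gene gating follows r and adjusted-P thresholds", {
  set.seed(30)
  n <- 300
  pc <- rnorm(n)
  v <- rbind(exact = pc,                           # r = 1
             corr = pc + rnorm(n, 0, 1),           # strong
             none = rnorm(n),                      # null
             flat = rep(1, n))                     # zero variance
  colnames(v) <- paste0("c", 1:n)
  res <- pc_associated_genes(make_expr(v), pc)
  expect_equal(res$n_zero_variance, 1)
  expect_equal(res$table$r[res$table$gene == "exact"], 1, tolerance = 1e-9)
  expect_true("exact" %in% res$selected$gene)
  expect_true("corr" %in% res$selected$gene)
  expect_false("none" %in% res$selected$gene)

  # null genes pass the adjusted-P filter at roughly alpha before r_min,
  # and a true-null gene fails the r_min screen at large n
  set.seed(31)
  vnull <- matrix(rnorm(200 * 1000), 200,
                  dimnames = list(paste0("g", 1:200), paste0("c", 1:1000)))
  pc2 <- rnorm(1000)
  res2 <- pc_associated_genes(make_expr(vnull), pc2, r_min = 0)
  expect_lt(nrow(res2$selected) / 200, 0.06)   # BH keeps FDR near alpha
  res3 <- pc_associated_genes(make_expr(vnull), pc2, r_min = 0.3)
  expect_equal(nrow(res3$selected), 0)
})
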