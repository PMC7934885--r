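test_that("Kaplan-Meier matches the hand product-limit on small tables", {
  # worked example: times (1,2,3), all events
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1), horizon = Inf)
  expect_equal(km$steps$surv, c(2 / 3, 1 / 3, 0))

  set.seed(50)
  for (i in 1:30) {
    n <- sample(2:5, 1)
    tm <- sample(1:4, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    km <- km_estimate(tm, ev, horizon = Inf)
    ref <- km_reference(tm, ev)
    got <- km$steps[km$steps$n_event > 0, ]
    expect_equal(got$surv, ref$surv, tolerance = 1e-12,
                 info = paste(tm, ev, collapse = ","))
  }

  # no events => survival identically 1
  km0 <- km_estimate(c(2, 5), c(0, 0))
  expect_true(all(km0$steps$surv == 1))
  # duplicating every record leaves the estimate unchanged
  tm <- c(1, 3, 4, 7); ev <- c(1, 0, 1, 1)
  a <- km_estimate(tm, ev, horizon = Inf)$steps
  b <- km_estimate(rep(tm, 2), rep(ev, 2), horizon = Inf)$steps
  expect_equal(b$surv, a$surv)
  # horizon truncation censors late events
  kmh <- km_estimate(c(10, 40), c(1, 1), horizon = 28)
  expect_true(all(kmh$steps$time <= 28))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank test behaves at the null and under strong effects", {
  # identical groups duplicated: statistic 0
  tm <- c(2, 4, 6, 9); ev <- c(1, 1, 0, 1)
  lr <- logrank_test(rep(tm, 2), rep(ev, 2), rep(c("A", "B"), each = 4))
  expect_lt(lr$chisq, 1e-9)
  expect_equal(lr$p, 1, tolerance = 1e-6)
  expect_error(logrank_test(tm, ev, rep("A", 4)), "2 groups")

  # power under a hazard ratio of 3 at n = 200
  set.seed(51)
  pow <- replicate(50, {
    g <- rep(c("A", "B"), each = 100)
    tm <- c(rexp(100, 1), rexp(100, 3))
    logrank_test(pmin(tm, 5), as.integer(tm <= 5), g)$p < 0.05
  })
  expect_gte(mean(pow), 0.9)
})

test_that("Cox fit matches a grid-search partial-likelihood oracle", {
  set.seed(52)
  n <- 30
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, exp(0.8 * x))
  tm <- tm + runif(n, 0, 1e-4)           # break ties
  ev <- rep(1, n)
  fit <- cox_fit(tm, ev, data.frame(x = x))
  b_ref <- cox_grid_mle(tm, ev, x)
  expect_equal(unname(log(fit$table$hr)), b_ref, tolerance = 5e-3)
})

test_that("Cox interface: SG2 reference, guards and CI coverage", {
  set.seed(53)
  sv <- generate_cohort(cohort_spec(n_patients = 300, seed = 53))$survival
  fit <- cox_fit(sv$time, sv$event,
                 sv[c("subtype_true", "age")] |>
                   stats::setNames(c("subtype", "age")))
  expect_true("subtypeSG1" %in% fit$table$term)  # SG2 is the reference
  expect_lt(fit$table$hr[fit$table$term == "subtypeSG1"], 1)

  expect_error(cox_fit(sv$time, sv$event, data.frame(k = rep(1, nrow(sv)))),
               "constant")

  # null covariate: 95% Wald CI covers HR = 1 at roughly nominal rate
  cover <- replicate(200, {
    n <- 80
    tm <- rexp(n); ev <- rbinom(n, 1, 0.8); z <- rnorm(n)
    tab <- cox_fit(tm, ev, data.frame(z = z))$table
    tab$lo95 <= 1 && 1 <= tab$hi95
  })
  expect_gt(mean(cover), 0.9)
})

test_that("time-binned rank-sum comparison finds late divergence only", {
  set.seed(54)
  bins <- c(0.5, 1, 4, 7, 14, 21, 28)
  mk <- function(strat, slow) {
    t <- rep(bins, each = 15) + rnorm(105, 0, 0.1)
    data.frame(time = t, stratum = strat,
               C1 = ifelse(t > 10, slow, 0) + rnorm(105, 0, 0.3))
  }
  traj <- rbind(mk("complicated", 2), mk("uncomplicated", 0))
  res <- binned_group_test(traj, bins)
  late <- res$bin >= 14
  expect_true(all(res$significant[late]))
  expect_true(all(res$direction[late] > 0))
  expect_lt(mean(res$significant[!late]), 0.5)

  # sparse bins are skipped with NA
  tiny <- data.frame(time = c(0.5, 0.5, 28), stratum = c("a", "b", "a"),
                     C1 = c(1, 2, 3))
  res2 <- binned_group_test(tiny, bins)
  expect_true(all(is.na(res2$p)))

  # exact small-sample p agrees with enumeration
  t3 <- data.frame(time = rep(7, 6), stratum = rep(c("a", "b"), 3),
                   C1 = c(5, 1, 9, 2, 7, 3))
  res3 <- binned_group_test(t3, bins = 7)
  x1 <- t3$C1[t3$stratum == "a"]; x2 <- t3$C1[t3$stratum == "b"]
  expect_equal(res3$p[!is.na(res3$p)], wilcox_enumerate(x1, x2))
})

test_that("cohort summary reports counts and a one-decimal mortality rate", {
  expect_equal(cohort_summary(rep(c("recovery", "death"),
                                  c(160, 7)))$mortality_pct, 4.2)
  s <- cohort_summary(data.frame(event_type = c("recovery", "death",
                                                "recovery")))
  expect_equal(s$deaths, 1)
  expect_equal(s$mortality_pct, 33.3)
  expect_equal(cohort_summary(rep("recovery", 10))$mortality_pct, 0)
  expect_error(cohort_summary(character(0)), "empty")
})
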