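#' Kaplan-Meier estimate, truncated at a horizon
#'
#' Product-limit estimator per group with administrative censoring at the
#' horizon (default 28 days), the standard window for visualizing
#' short-term prognosis.
#'
#' @param time event/censoring times (days), positive.
#' @param event 0/1 event indicator.
#' @param group optional grouping vector; `NULL` = one group.
#' @param horizon administrative censoring time in days (default 28;
#'   `Inf` disables truncation).
#' @return List with `steps` (data frame: group, time, n_risk, n_event,
#'   n_censor, surv) and `fit` (the underlying `survfit` object).
#' @export
km_estimate <- function(time, event, group = NULL, horizon = 28) {
  if (any(time < 0)) stop("negative times")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (is.null(group)) group <- rep("all", length(time))
  stopifnot(length(time) == length(event), length(time) == length(group))
  over <- time > horizon
  event[over] <- 0
  time[over] <- horizon
  df <- data.frame(time = time, event = event, group = factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(df$group)[1], length(s$time))
         else sub("^group=", "", as.character(s$strata))
  steps <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                      n_event = s$n.event, n_censor = s$n.censor,
                      surv = s$surv, stringsAsFactors = FALSE)
  list(steps = steps, fit = fit)
}

#' Log-rank test between survival curves
#'
#' @param time,event as in [km_estimate()].
#' @param group grouping with >= 2 levels.
#' @return List with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("log-rank test requires >= 2 groups")
  if (any(time < 0)) stop("negative times")
  df <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = nlevels(group) - 1, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), df = nlevels(group) - 1, p = p)
}

#' Cox proportional-hazards fit with Efron tie handling
#'
#' Partial-likelihood fit of `Surv(time, event)` on the supplied
#' covariates. A `subtype` column is releveled so SG2 is the reference,
#' making the reported hazard ratio "SG1 vs SG2" — for a recovery event, an
#' HR below 1 means SG1 recovers more slowly. Wald confidence intervals.
#'
#' @param time,event as in [km_estimate()].
#' @param covariates data frame of covariates (one row per subject);
#'   factors are handled by the usual treatment coding.
#' @return List of class `CoxFit`: `table` (term, hr, lo95, hi95, p),
#'   `model` (the `coxph` fit), `n_events`.
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(time))
    stop("covariates must have one row per subject")
  const <- vapply(covariates, function(x) length(unique(x)) < 2, logical(1))
  if (any(const))
    stop("constant covariate(s): ", paste(names(covariates)[const],
                                          collapse = ", "))
  if ("subtype" %in% names(covariates))
    covariates$subtype <- stats::relevel(factor(covariates$subtype),
                                         ref = "SG2")
  if (sum(event) < ncol(covariates))
    warning("fewer events than covariates; estimates may be unstable")
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = "efron"),
    error = function(e) stop("Cox model failed to converge: ",
                             conditionMessage(e)))
  if (any(abs(stats::coef(fit)) > 10))
    warning("very large coefficient(s); possible separation")
  sm <- summary(fit)
  tab <- data.frame(term = rownames(sm$coefficients),
                    hr = sm$conf.int[, "exp(coef)"],
                    lo95 = sm$conf.int[, "lower .95"],
                    hi95 = sm$conf.int[, "upper .95"],
                    p = sm$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, model = fit, n_events = sum(event)),
            class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat("Cox proportional hazards (Efron ties),", x$n_events, "events\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Time-binned rank-sum comparison of score trajectories
#'
#' Assigns every sample to the nearest of the nominal time bins (half-open
#' intervals with boundaries midway between bin centers) and compares the
#' two outcome strata within each bin by Wilcoxon rank-sum, per signature.
#' Bins with fewer than 2 samples in either stratum are skipped and
#' reported.
#'
#' @param traj data frame with columns `time` (same units as `bins`),
#'   `stratum` (two levels, e.g. complicated vs noncomplicated), and one
#'   numeric column per signature score.
#' @param bins ordered bin centers; default the 7 standard post-injury
#'   points 0.5, 1, 4, 7, 14, 21, 28 days.
#' @param score_cols names of the score columns; default every numeric
#'   column other than `time`.
#' @return Data frame: signature, bin, n per stratum, p, direction
#'   (sign of the stratum-1 minus stratum-2 median difference), significant
#'   flag at p < 0.05; skipped bins carry NA p.
#' @export
binned_group_test <- function(traj, bins = c(0.5, 1, 4, 7, 14, 21, 28),
                              score_cols = NULL) {
  stopifnot(all(c("time", "stratum") %in% names(traj)))
  if (is.unsorted(bins)) stop("bins must be ordered")
  stratum <- factor(traj$stratum)
  if (nlevels(stratum) != 2) stop("exactly 2 strata are required")
  if (is.null(score_cols)) {
    num <- vapply(traj, is.numeric, logical(1))
    score_cols <- setdiff(names(traj)[num], "time")
  }
  # nearest-center assignment via midpoints
  cuts <- c(-Inf, (bins[-1] + bins[-length(bins)]) / 2, Inf)
  bin_of <- bins[findInterval(traj$time, cuts, rightmost.closed = FALSE)]
  lv <- levels(stratum)
  out <- list()
  for (sc in score_cols) for (b in bins) {
    sel <- bin_of == b
    x1 <- traj[[sc]][sel & stratum == lv[1]]
    x2 <- traj[[sc]][sel & stratum == lv[2]]
    if (length(x1) < 2 || length(x2) < 2) {
      out[[length(out) + 1L]] <-
        data.frame(signature = sc, bin = b, n1 = length(x1),
                   n2 = length(x2), p = NA_real_, direction = NA_integer_,
                   significant = NA, stringsAsFactors = FALSE)
      next
    }
    p <- suppressWarnings(stats::wilcox.test(x1, x2)$p.value)
    out[[length(out) + 1L]] <-
      data.frame(signature = sc, bin = b, n1 = length(x1), n2 = length(x2),
                 p = p,
                 direction = sign(stats::median(x1) - stats::median(x2)),
                 significant = p < 0.05, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Cohort outcome summary
#'
#' Death and survivor counts plus the in-hospital mortality rate as a
#' percentage rounded to one decimal.
#'
#' @param surv a survival table with an `event_type` column
#'   (recovery/death), or a logical/character vector of death indicators.
#' @return List: `n`, `deaths`, `alive`, `mortality_pct`.
#' @examples
#' cohort_summary(rep(c("recovery", "death"), c(160, 7)))$mortality_pct  # 4.2
#' @export
cohort_summary <- function(surv) {
  et <- if (is.data.frame(surv)) surv$event_type else surv
  if (length(et) == 0) stop("empty survival table")
  dead <- if (is.logical(et)) et else et == "death"
  n <- length(dead)
  deaths <- sum(dead)
  list(n = n, deaths = deaths, alive = n - deaths,
       mortality_pct = round(100 * deaths / n, 1))
}
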