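# Survival machinery: Kaplan-Meier, log-rank, Cox PH wrappers, censoring-
# weighted time-dependent AUC, Harrell's C-index, and baseline comparisons.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the DMFS function; at tied times, events
#' precede censorings, so censored-at-t subjects remain in the risk set at t.
#'
#' @param records Survival records (`time_months`, `event`).
#' @param conf.int Include a 95% CI band (log transform).
#' @return An object of class `km_curve`: data frame with `time`,
#'   `n_risk`, `n_event`, `survival`, and optionally `lower`, `upper`.
#' @export
km_estimate <- function(records, conf.int = TRUE) {
  check_records(records)
  assert_that(nrow(records) >= 1, "need at least one record")
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1, data = records,
    conf.type = if (conf.int) "log" else "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  if (conf.int) {
    out$lower <- fit$lower
    out$upper <- fit$upper
  }
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function lookup; S(t) = 1 before the first event.
#'
#' @param km A `km_curve` (or any data frame with `time` and `survival`).
#' @param times Numeric vector of evaluation times.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, times) {
  vapply(times, function(t) {
    idx <- which(km$time <= t)
    if (length(idx) == 0L) 1 else km$survival[max(idx)]
  }, 0)
}

#' Two-group log-rank test
#'
#' Standard two-sided log-rank chi-square test (1 df) comparing DMFS between
#' two groups.
#'
#' @param group_a,group_b Survival records of the two groups.
#' @return List with `statistic` and `p`.
#' @export
logrank_test <- function(group_a, group_b) {
  check_records(group_a); check_records(group_b)
  assert_that(nrow(group_a) > 0 && nrow(group_b) > 0,
              "both groups must be non-empty")
  dat <- rbind(
    data.frame(time_months = group_a$time_months, event = group_a$event,
               g = 0L),
    data.frame(time_months = group_b$time_months, event = group_b$event,
               g = 1L))
  if (sum(dat$event) == 0L) {
    warning("no events in either group: log-rank p set to 1")
    return(list(statistic = 0, p = 1))
  }
  sd_ <- survival::survdiff(survival::Surv(time_months, event) ~ g,
                            data = dat)
  list(statistic = unname(sd_$chisq),
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Multivariable Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation with Efron tie handling; reports per
#' covariate the hazard ratio, 95% CI (`exp(beta +- 1.96 se)`) and Wald p.
#'
#' @param covariate_table Data frame of covariates (numeric or factor; no
#'   constant columns).
#' @param records Survival records aligned row-wise with `covariate_table`.
#' @return An object of class `cox_fit`: list with the `coxph` fit, a
#'   `table` (coef, HR, CI, p), coefficients and covariance.
#' @export
fit_cox <- function(covariate_table, records) {
  check_records(records)
  assert_that(is.data.frame(covariate_table) && ncol(covariate_table) >= 1,
              "`covariate_table` must be a non-empty data frame")
  const <- vapply(covariate_table,
                  function(x) length(unique(x)) < 2L, TRUE)
  assert_that(!any(const),
              paste("constant covariate(s):",
                    paste(names(covariate_table)[const], collapse = ", ")))
  if (sum(records$event) < ncol(covariate_table))
    warning("fewer events than covariates: estimates may be unstable")
  dat <- cbind(covariate_table,
               .time = records$time_months, .event = records$event)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariate_table)), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = "efron"),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e),
                             call. = FALSE))
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)))
    stop("Cox fit did not converge for covariate(s): ",
         paste(names(beta)[!is.finite(beta)], collapse = ", "))
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(
    covariate = names(beta), coef = unname(beta), se = unname(se),
    hr = exp(unname(beta)),
    hr_lower = exp(unname(beta) - 1.96 * unname(se)),
    hr_upper = exp(unname(beta) + 1.96 * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
    stringsAsFactors = FALSE)
  structure(list(fit = fit, table = tab, coefficients = beta,
                 vcov = stats::vcov(fit)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties)\n")
  tab <- x$table
  tab$`HR (95% CI)` <- sprintf("%.3f (%.3f-%.3f)", tab$hr, tab$hr_lower,
                               tab$hr_upper)
  print(tab[, c("covariate", "coef", "HR (95% CI)", "p")], row.names = FALSE)
  invisible(x)
}

#' Censoring distribution (KM of the censoring indicator)
#' @noRd
censoring_km <- function(records) {
  cens <- records
  cens$event <- 1 - cens$event
  km_estimate(cens, conf.int = FALSE)
}

#' Time-dependent AUC with inverse-probability-of-censoring weights
#'
#' Cumulative-case / dynamic-control AUC at each horizon: cases are subjects
#' with an observed event by t, controls those still event-free beyond t.
#' Cases are weighted by `1/G(T_i-)` and controls by `1/G(t)`, where G is
#' the Kaplan-Meier estimate of the censoring distribution; tied marker
#' values count 1/2.
#'
#' @param marker Numeric risk marker (higher = higher risk).
#' @param records Survival records aligned with `marker`.
#' @param horizons Evaluation times in months (default 12, 24, 36).
#' @return Named numeric vector of AUCs, one per horizon.
#' @export
time_dependent_auc <- function(marker, records, horizons = c(12, 24, 36)) {
  check_records(records)
  assert_that(length(marker) == nrow(records),
              "`marker` length must match `records`")
  assert_that(all(is.finite(marker)), "marker must be finite")
  G <- censoring_km(records)
  t_obs <- records$time_months
  d <- records$event
  vapply(stats::setNames(horizons, paste0("t", horizons)), function(h) {
    assert_that(h <= max(t_obs),
                sprintf("horizon %g exceeds follow-up (max %g)", h,
                        max(t_obs)))
    case <- which(t_obs <= h & d == 1)
    ctrl <- which(t_obs > h)
    assert_that(length(case) > 0,
                sprintf("no events by horizon %g", h))
    assert_that(length(ctrl) > 0,
                sprintf("no controls beyond horizon %g", h))
    # left limit G(T-): evaluate just before the case's time
    w_case <- 1 / pmax(km_survival_at(G, t_obs[case] - 1e-9), 1e-12)
    w_ctrl <- rep(1 / pmax(km_survival_at(G, h), 1e-12), length(ctrl))
    mc <- marker[case]; mk <- marker[ctrl]
    num <- 0; den <- 0
    for (i in seq_along(case)) {
      conc <- sum(w_ctrl * (mc[i] > mk)) + 0.5 * sum(w_ctrl * (mc[i] == mk))
      num <- num + w_case[i] * conc
      den <- den + w_case[i] * sum(w_ctrl)
    }
    num / den
  }, 0)
}

#' Harrell's concordance index
#'
#' Fraction of usable patient pairs whose marker ordering agrees with their
#' survival ordering: a pair is usable if the shorter observed time is an
#' event; tied markers count 1/2. The 95% CI uses an asymptotic normal
#' (Noether-type) standard error from the pair counts.
#'
#' @param marker Numeric risk marker (higher = earlier event expected).
#' @param records Survival records aligned with `marker`.
#' @return List with `c`, `se`, `lower`, `upper`, `n_pairs`.
#' @export
harrell_cindex <- function(marker, records) {
  check_records(records)
  n <- nrow(records)
  assert_that(length(marker) == n, "`marker` length must match `records`")
  t_ <- records$time_months
  d <- records$event
  conc <- disc <- tied <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    # usable: earlier time is an observed event (strictly earlier, or tied
    # times with exactly one event are compared against the survivor)
    ti <- t_[i]; di <- d[i]
    usable_i <- di == 1 & t_[j] > ti
    usable_j <- d[j] == 1 & ti > t_[j]
    if (any(usable_i)) {
      mj <- marker[j][usable_i]
      conc <- conc + sum(marker[i] > mj)
      disc <- disc + sum(marker[i] < mj)
      tied <- tied + sum(marker[i] == mj)
    }
    if (any(usable_j)) {
      mj <- marker[j][usable_j]
      conc <- conc + sum(mj > marker[i])
      disc <- disc + sum(mj < marker[i])
      tied <- tied + sum(mj == marker[i])
    }
  }
  npairs <- conc + disc + tied
  assert_that(npairs > 0, "no usable pairs for concordance")
  c_ <- (conc + 0.5 * tied) / npairs
  se <- sqrt(c_ * (1 - c_) / npairs)
  list(c = c_, se = se, lower = max(0, c_ - 1.96 * se),
       upper = min(1, c_ + 1.96 * se), n_pairs = npairs)
}

#' Baseline-characteristics comparison between two cohorts
#'
#' Continuous variables: two-sample t test if both samples pass a Shapiro
#' normality screen at 0.05, otherwise Mann-Whitney U. Categorical
#' variables: chi-square unless any expected cell count is < 5, then
#' Fisher's exact test. All two-sided.
#'
#' @param table_a,table_b Data frames with identical columns.
#' @param types Optional named character vector (`"continuous"` /
#'   `"categorical"`); by default numeric columns are continuous and
#'   factor/character columns categorical.
#' @param shapiro_alpha Normality-screen level (default 0.05).
#' @return Data frame with `variable`, `test`, `p`.
#' @export
compare_baselines <- function(table_a, table_b, types = NULL,
                              shapiro_alpha = 0.05) {
  vars <- intersect(names(table_a), names(table_b))
  assert_that(length(vars) > 0, "no common variables to compare")
  rows <- lapply(vars, function(v) {
    a <- table_a[[v]]; b <- table_b[[v]]
    type <- if (!is.null(types) && v %in% names(types)) types[[v]]
            else if (is.numeric(a)) "continuous" else "categorical"
    if (type == "continuous") {
      normal <- function(x) {
        if (length(unique(x)) < 3L) return(FALSE)
        x <- if (length(x) > 5000) sample(x, 5000) else x
        stats::shapiro.test(x)$p.value >= shapiro_alpha
      }
      if (normal(a) && normal(b)) {
        data.frame(variable = v, test = "t",
                   p = stats::t.test(a, b)$p.value)
      } else {
        data.frame(variable = v, test = "mann-whitney",
                   p = stats::wilcox.test(a, b, exact = FALSE)$p.value)
      }
    } else {
      lev <- union(unique(as.character(a)), unique(as.character(b)))
      assert_that(length(lev) >= 1, sprintf("variable %s has no levels", v))
      tab <- rbind(table(factor(as.character(a), levels = lev)),
                   table(factor(as.character(b), levels = lev)))
      if (length(lev) < 2L)
        return(data.frame(variable = v, test = "chi-square", p = 1))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        data.frame(variable = v, test = "fisher",
                   p = stats::fisher.test(tab)$p.value)
      } else {
        data.frame(variable = v, test = "chi-square",
                   p = stats::chisq.test(tab, correct = FALSE)$p.value)
      }
    }
  })
  do.call(rbind, rows)
}
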