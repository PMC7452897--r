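# Cox nomograms, horizon-specific DMFS predictions, calibration curves,
# decision-curve analysis, and reclassification measures (NRI, IDI).

#' Build a Cox nomogram
#'
#' Fits a Cox proportional-hazards model and attaches (i) the Breslow
#' baseline survival at the requested horizons and (ii) a 0-100 point scale:
#' each covariate's points are its linear-predictor contribution shifted to
#' be non-negative and scaled so the largest absolute contribution spans 100
#' points. Predictions from total points reproduce the Cox model's
#' predictions exactly.
#'
#' @param covariates Data frame of covariates (signature score and/or
#'   clinical factors).
#' @param records Survival records aligned with `covariates`.
#' @param horizons Prediction horizons in months (default 12, 24, 36).
#' @return An object of class `nomogram_model`.
#' @export
build_nomogram <- function(covariates, records, horizons = c(12, 24, 36)) {
  cf <- fit_cox(covariates, records)
  fit <- cf$fit
  # uncentered baseline: H0(t) for all covariates at 0
  bh <- survival::basehaz(fit, centered = FALSE)
  lp <- unname(stats::predict(fit, type = "lp", reference = "zero"))
  X <- stats::model.matrix(fit)
  beta <- stats::coef(fit)
  contrib <- sweep(X, 2L, beta, `*`)
  ref <- apply(contrib, 2L, min)       # covariate value worth 0 points
  ranges <- apply(contrib, 2L, max) - ref
  max_range <- max(ranges)
  assert_that(max_range > 0, "all covariate contributions are constant")
  points_scale <- 100 / max_range      # points per unit log-hazard
  structure(list(cox = cf, horizons = horizons, basehaz = bh,
                 point_ref = ref, points_scale = points_scale,
                 lp = lp, records = records),
            class = "nomogram_model")
}

#' @export
print.nomogram_model <- function(x, ...) {
  cat("Cox nomogram\n")
  print(x$cox)
  cat(sprintf("  point scale: %.4f points per unit log-hazard; horizons: %s months\n",
              x$points_scale, paste(x$horizons, collapse = "/")))
  invisible(x)
}

#' Per-subject nomogram points
#'
#' @param model A [nomogram_model].
#' @param covariates Data frame of covariates (default: training data).
#' @return Matrix of per-covariate points plus a `total` column.
#' @export
nomogram_points <- function(model, covariates = NULL) {
  fit <- model$cox$fit
  X <- if (is.null(covariates)) stats::model.matrix(fit)
       else stats::model.matrix(stats::delete.response(stats::terms(fit)),
                                data = covariates)[, names(stats::coef(fit)),
                                                   drop = FALSE]
  contrib <- sweep(X, 2L, stats::coef(fit), `*`)
  pts <- sweep(contrib, 2L, model$point_ref, `-`) * model$points_scale
  cbind(pts, total = rowSums(pts))
}

#' Baseline cumulative hazard at a time (step function)
#' @noRd
basehaz_at <- function(bh, t) {
  idx <- which(bh$time <= t)
  if (length(idx) == 0L) 0 else bh$hazard[max(idx)]
}

#' Predict DMFS probability at a horizon
#'
#' `S(t | x) = S0(t) ^ exp(lp)` with the Breslow baseline `S0` and the
#' uncentered linear predictor. Monotone non-increasing in both the linear
#' predictor and the horizon.
#'
#' @param model A [nomogram_model].
#' @param covariates Data frame of new covariate rows (default: training
#'   data). Unseen factor levels raise an error.
#' @param horizon Months (must not exceed observed follow-up).
#' @return Numeric vector of survival probabilities in `[0, 1]`.
#' @export
predict_dmfs <- function(model, covariates = NULL, horizon = 36) {
  assert_that(horizon > 0, "`horizon` must be positive")
  assert_that(horizon <= max(model$basehaz$time),
              sprintf("horizon %g exceeds observed follow-up", horizon))
  lp <- if (is.null(covariates)) model$lp
        else unname(stats::predict(model$cox$fit, newdata = covariates,
                                   type = "lp", reference = "zero"))
  h0 <- basehaz_at(model$basehaz, horizon)
  exp(-h0)^exp(lp)
}

#' Calibration curve at a horizon
#'
#' Bins subjects into `n_groups` quantile groups of predicted survival and
#' compares each group's mean prediction with its Kaplan-Meier estimate (and
#' 95% CI) at the horizon. If all predictions are equal the curve collapses
#' to a single group with a warning.
#'
#' @param predictions Predicted survival probabilities at `horizon`.
#' @param records Survival records aligned with `predictions`.
#' @param horizon Months.
#' @param n_groups Number of quantile bins (default 5).
#' @return Data frame with `group`, `n`, `predicted`, `observed`, `lower`,
#'   `upper`.
#' @export
calibration_curve <- function(predictions, records, horizon, n_groups = 5) {
  check_records(records)
  assert_that(n_groups >= 2, "`n_groups` must be at least 2")
  assert_that(length(predictions) == nrow(records),
              "`predictions` length must match `records`")
  qs <- unique(stats::quantile(predictions, probs = seq(0, 1,
                                                        length.out = n_groups + 1)))
  if (length(qs) < 3L) {
    warning("degenerate predictions: falling back to a single group")
    grp <- factor(rep(1L, length(predictions)))
  } else {
    grp <- cut(predictions, breaks = qs, include.lowest = TRUE,
               labels = FALSE)
    grp <- factor(grp)
  }
  rows <- lapply(levels(grp), function(g) {
    sel <- grp == g
    km <- km_estimate(records[sel, , drop = FALSE])
    s_obs <- km_survival_at(km, horizon)
    lo <- if (nrow(km) && !is.null(km$lower)) {
      idx <- which(km$time <= horizon)
      if (length(idx)) km$lower[max(idx)] else 1
    } else NA_real_
    hi <- if (nrow(km) && !is.null(km$upper)) {
      idx <- which(km$time <= horizon)
      if (length(idx)) km$upper[max(idx)] else 1
    } else NA_real_
    data.frame(group = as.integer(g), n = sum(sel),
               predicted = mean(predictions[sel]), observed = s_obs,
               lower = lo, upper = hi)
  })
  do.call(rbind, rows)
}

#' Decision-curve analysis
#'
#' Net benefit of acting on predicted event risk at each threshold:
#' `NB(pt) = TP/n - FP/n * pt / (1 - pt)`, where a subject is test-positive
#' if the predicted event risk at the horizon is >= pt, and the event status
#' of censored subjects is estimated by the Kaplan-Meier survival of the
#' test-positive (resp. all) subjects at the horizon. Includes treat-all and
#' treat-none (= 0) references.
#'
#' @param predictions_of_event Predicted event probabilities by `horizon`.
#' @param records Survival records aligned with `predictions_of_event`.
#' @param horizon Months.
#' @param thresholds Risk thresholds in (0, 1).
#' @return Data frame with `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
decision_curve <- function(predictions_of_event, records, horizon,
                           thresholds = seq(0.05, 0.6, by = 0.05)) {
  check_records(records)
  assert_that(all(thresholds > 0 & thresholds < 1),
              "thresholds must lie strictly inside (0, 1)")
  n <- nrow(records)
  km_all <- km_estimate(records, conf.int = FALSE)
  p_all <- 1 - km_survival_at(km_all, horizon)
  rows <- lapply(thresholds, function(pt) {
    odds <- pt / (1 - pt)
    pos <- predictions_of_event >= pt
    nb <- if (!any(pos)) 0 else {
      km_pos <- km_estimate(records[pos, , drop = FALSE], conf.int = FALSE)
      p_pos <- 1 - km_survival_at(km_pos, horizon)
      (sum(pos) / n) * p_pos - (sum(pos) / n) * (1 - p_pos) * odds
    }
    data.frame(threshold = pt, net_benefit = nb,
               treat_all = p_all - (1 - p_all) * odds, treat_none = 0)
  })
  do.call(rbind, rows)
}

#' KM-based event-status weights at a horizon
#'
#' Observed event by t: 1. Still at risk beyond t: 0. Censored at c < t:
#' conditional event probability `(S(c) - S(t)) / S(c)` from the overall KM.
#' @noRd
event_weights <- function(records, horizon) {
  km <- km_estimate(records, conf.int = FALSE)
  s_h <- km_survival_at(km, horizon)
  w <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    ti <- records$time_months[i]
    if (ti > horizon) w[i] <- 0
    else if (records$event[i] == 1) w[i] <- 1
    else {
      s_c <- km_survival_at(km, ti)
      w[i] <- if (s_c > 0) (s_c - s_h) / s_c else 0
    }
  }
  pmin(pmax(w, 0), 1)
}

#' Continuous net reclassification improvement
#'
#' Category-free NRI of `pred_new` over `pred_old` (both predicted event
#' risks by `horizon`):
#' `NRI = P(up|event) - P(down|event) + P(down|non-event) - P(up|non-event)`,
#' with event status under censoring estimated by subgroup Kaplan-Meier at
#' the horizon (up-movers, down-movers, overall).
#'
#' @param pred_old,pred_new Predicted event risks from the two models, same
#'   subjects.
#' @param records Survival records aligned with the predictions.
#' @param horizon Months (default 36).
#' @return List with `nri`, `nri_event`, `nri_nonevent`, `horizon`.
#' @export
compute_nri <- function(pred_old, pred_new, records, horizon = 36) {
  check_records(records)
  n <- nrow(records)
  assert_that(length(pred_old) == n && length(pred_new) == n,
              "prediction vectors must match `records`")
  up <- pred_new > pred_old
  down <- pred_new < pred_old
  if (!any(up) && !any(down)) {
    warning("no reclassification movement: NRI = 0")
    return(list(nri = 0, nri_event = 0, nri_nonevent = 0, horizon = horizon))
  }
  p_event_in <- function(sel) {
    if (!any(sel)) return(0)
    km <- km_estimate(records[sel, , drop = FALSE], conf.int = FALSE)
    1 - km_survival_at(km, horizon)
  }
  p_all <- p_event_in(rep(TRUE, n))
  assert_that(p_all > 0 && p_all < 1,
              "horizon must see both events and survivors")
  p_up <- mean(up); p_down <- mean(down)
  pe_up <- p_event_in(up); pe_down <- p_event_in(down)
  nri_event <- (p_up * pe_up - p_down * pe_down) / p_all
  nri_nonevent <- (p_down * (1 - pe_down) - p_up * (1 - pe_up)) / (1 - p_all)
  list(nri = nri_event + nri_nonevent, nri_event = nri_event,
       nri_nonevent = nri_nonevent, horizon = horizon)
}

#' Integrated discrimination improvement
#'
#' Difference in discrimination slope between the two models:
#' `IDI = [mean(new | event) - mean(new | non-event)] -
#'        [mean(old | event) - mean(old | non-event)]`,
#' where the event/non-event means are weighted by each subject's KM-based
#' probability of being an event by the horizon (1 for observed events, 0
#' for subjects still at risk, conditional probability for early censoring).
#'
#' @inheritParams compute_nri
#' @return List with `idi`, `slope_old`, `slope_new`, `horizon`.
#' @export
compute_idi <- function(pred_old, pred_new, records, horizon = 36) {
  check_records(records)
  n <- nrow(records)
  assert_that(length(pred_old) == n && length(pred_new) == n,
              "prediction vectors must match `records`")
  w <- event_weights(records, horizon)
  assert_that(sum(w) > 0 && sum(1 - w) > 0,
              "horizon must see both events and survivors")
  slope <- function(p)
    sum(w * p) / sum(w) - sum((1 - w) * p) / sum(1 - w)
  s_old <- slope(pred_old)
  s_new <- slope(pred_new)
  list(idi = s_new - s_old, slope_old = s_old, slope_new = s_new,
       horizon = horizon)
}
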