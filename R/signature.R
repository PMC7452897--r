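# Coarse-to-fine feature selection and the LASSO-Cox radiomic signature.
#
# Selection chain on the primary cohort: (1) univariate Cox screen of every
# feature; (2) coarse filter keeping the smallest-p features (top `fraction`
# of all features, intersected with p < alpha); (3) greedy correlation
# pruning at |r| > cutoff; (4) L1-penalised Cox with cross-validated lambda.
# The signature score is the penalised linear predictor of the normalised
# features; patients are stratified at the primary-cohort median score.

#' Z-score normalise feature columns
#'
#' On the primary cohort, fits per-feature mean and standard deviation and
#' standardises; on validation cohorts, the *stored primary-cohort* stats
#' must be supplied so that signature scores and the median cutoff remain
#' portable (validation data are never re-normalised by themselves).
#'
#' @param table Feature table (data frame; a `patient_id` column is carried
#'   through untouched).
#' @param stats Optional named list `list(mean = ..., sd = ...)` of reference
#'   statistics; if `NULL`, statistics are fitted from `table`.
#' @return The normalised table, with the statistics in `attr(, "stats")`.
#' @export
normalize_features <- function(table, stats = NULL) {
  feats <- setdiff(names(table), "patient_id")
  if (is.null(stats)) {
    mu <- vapply(table[feats], mean, 0)
    sd_ <- vapply(table[feats], stats::sd, 0)
    assert_that(all(sd_ > 0),
                paste("constant feature(s):",
                      paste(utils::head(feats[sd_ == 0], 5), collapse = ", ")))
    stats <- list(mean = mu, sd = sd_)
  } else {
    missing <- setdiff(feats, names(stats$mean))
    assert_that(length(missing) == 0L,
                paste("features absent from reference stats:",
                      paste(utils::head(missing, 5), collapse = ", ")))
  }
  for (f in feats)
    table[[f]] <- (table[[f]] - stats$mean[[f]]) / stats$sd[[f]]
  attr(table, "stats") <- stats
  table
}

#' Univariate Cox screen of every feature
#'
#' One single-covariate proportional-hazards fit per feature (Efron tie
#' handling) against DMFS; features for which the fit degenerates (zero
#' variance, non-convergence) get p = 1 with a warning, which drops them at
#' the coarse-filter stage.
#'
#' @param features Feature table (data frame, `patient_id` ignored).
#' @param records Survival records with `time_months`, `event` (same row
#'   order as `features`).
#' @return Data frame with columns `feature`, `beta`, `p`.
#' @export
univariate_cox_screen <- function(features, records) {
  check_records(records)
  assert_that(sum(records$event) >= 2, "need at least 2 events to screen")
  feats <- setdiff(names(features), "patient_id")
  y <- survival::Surv(records$time_months, records$event)
  n_bad <- 0L
  res <- lapply(feats, function(f) {
    x <- features[[f]]
    if (stats::sd(x) == 0) {
      n_bad <<- n_bad + 1L
      return(c(NA_real_, 1))
    }
    fit <- tryCatch({
      m <- survival::coxph(y ~ x, ties = "efron")
      s <- summary(m)
      c(unname(stats::coef(m)), s$coefficients[1, "Pr(>|z|)"])
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !all(is.finite(fit))) {
      n_bad <<- n_bad + 1L
      return(c(NA_real_, 1))
    }
    fit
  })
  if (n_bad > 0)
    warning(sprintf("%d feature(s) failed the univariate screen; p set to 1",
                    n_bad))
  out <- do.call(rbind, res)
  data.frame(feature = feats, beta = out[, 1], p = out[, 2],
             stringsAsFactors = FALSE)
}

#' Coarse filter on univariate p-values
#'
#' Keeps the features with `p < alpha` intersected with the
#' `ceiling(fraction * total)` smallest p-values (ranked ascending; ties
#' broken by the stable input order). `mode = "subset"` instead takes the top
#' `fraction` of the `p < alpha` subset.
#'
#' @param pvalues Named numeric vector of p-values (names = features), or the
#'   data frame returned by [univariate_cox_screen()].
#' @param fraction Fraction retained (default 0.20).
#' @param alpha Significance cutoff (default 0.1).
#' @param mode `"intersection"` (default) or `"subset"`.
#' @return Character vector of surviving feature names (possibly empty).
#' @export
coarse_filter <- function(pvalues, fraction = 0.20, alpha = 0.1,
                          mode = c("intersection", "subset")) {
  mode <- match.arg(mode)
  if (is.data.frame(pvalues))
    pvalues <- stats::setNames(pvalues$p, pvalues$feature)
  assert_that(fraction > 0 && fraction <= 1, "`fraction` must be in (0, 1]")
  sig <- names(pvalues)[pvalues < alpha]
  if (mode == "intersection") {
    k <- ceiling(fraction * length(pvalues))
    top <- names(pvalues)[order(pvalues)[seq_len(min(k, length(pvalues)))]]
    out <- intersect(top, sig)
  } else {
    k <- ceiling(fraction * length(sig))
    psub <- pvalues[sig]
    out <- names(psub)[order(psub)[seq_len(min(k, length(psub)))]]
  }
  # preserve stable catalog order
  names(pvalues)[names(pvalues) %in% out]
}

#' Greedy correlation pruning
#'
#' Repeatedly finds the feature pair with the largest absolute Pearson
#' correlation above `cutoff` (ties: first pair in lexicographic name order)
#' and removes the member with the larger mean absolute correlation against
#' all currently retained features (ties: the later column). Terminates with
#' max off-diagonal |r| <= cutoff. Constant columns correlate 0 with
#' everything (warning).
#'
#' @param feature_table Data frame of candidate features (`patient_id`
#'   ignored); >= 3 rows.
#' @param cutoff Absolute-correlation threshold (default 0.6).
#' @return Character vector of retained feature names, in input order.
#' @export
correlation_prune <- function(feature_table, cutoff = 0.6) {
  feats <- setdiff(names(feature_table), "patient_id")
  assert_that(nrow(feature_table) >= 3, "need at least 3 samples")
  if (length(feats) < 2L) return(feats)
  x <- as.matrix(feature_table[feats])
  const <- apply(x, 2, stats::sd) == 0
  if (any(const))
    warning(sprintf("%d constant feature(s): correlations defined as 0",
                    sum(const)))
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  keep <- feats
  while (length(keep) > 1L) {
    sub <- abs(r[keep, keep, drop = FALSE])
    mx <- max(sub)
    if (mx <= cutoff) break
    hits <- which(sub == mx, arr.ind = TRUE)
    pairs <- cbind(rownames(sub)[hits[, 1]], colnames(sub)[hits[, 2]])
    pairs <- t(apply(pairs, 1, sort))
    pairs <- unique(pairs)
    ord <- order(pairs[, 1], pairs[, 2])
    a <- pairs[ord[1], 1]; b <- pairs[ord[1], 2]
    mac <- rowMeans(sub)[c(a, b)]
    drop_ <- if (mac[1] > mac[2]) a
             else if (mac[2] > mac[1]) b
             else c(a, b)[max(match(c(a, b), feats)) == match(c(a, b), feats)]
    keep <- setdiff(keep, drop_)
  }
  keep
}

#' L1-penalised Cox fit with cross-validated lambda
#'
#' Fits the LASSO-Cox path on (already normalised) candidate features and
#' picks lambda by `n_folds`-fold cross-validated partial-likelihood deviance
#' (fold assignment seeded, so the fit is deterministic given `seed`).
#' The default `lambda_rule = "lambda.1se"` — the sparsest model within one
#' standard error of the minimum-deviance lambda — favours compact
#' signatures; `"lambda.min"` takes the minimum itself. Features with
#' non-zero coefficients at the chosen lambda form the signature. If only
#' one candidate is supplied, an unpenalised Cox coefficient is used (the
#' penalty has nothing to select).
#'
#' @param feature_table Normalised feature table (`patient_id` ignored).
#' @param records Survival records aligned with `feature_table`.
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Fold-assignment seed.
#' @param lambda Optional fixed penalty overriding the cross-validated
#'   choice.
#' @param lambda_rule Cross-validation rule: `"lambda.1se"` (default) or
#'   `"lambda.min"`.
#' @return List with `selected_features`, `coefficients`, `lambda`, `seed`.
#' @export
fit_lasso_cox <- function(feature_table, records, n_folds = 10, seed = 1L,
                          lambda = NULL,
                          lambda_rule = c("lambda.1se", "lambda.min")) {
  lambda_rule <- match.arg(lambda_rule)
  check_records(records)
  assert_that(sum(records$event) >= 2, "need at least 2 events")
  feats <- setdiff(names(feature_table), "patient_id")
  assert_that(length(feats) >= 1, "no candidate features")
  y <- survival::Surv(records$time_months, records$event)
  if (length(feats) == 1L) {
    m <- survival::coxph(y ~ x, data = data.frame(x = feature_table[[feats]]))
    return(list(selected_features = feats,
                coefficients = stats::setNames(unname(stats::coef(m)), feats),
                lambda = 0, seed = as.integer(seed)))
  }
  x <- as.matrix(feature_table[feats])
  if (is.null(lambda)) {
    foldid <- with_seed(seed,
                        sample(rep(seq_len(n_folds), length.out = nrow(x))))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", type.measure = "deviance",
                            foldid = foldid)
    lambda <- cv[[lambda_rule]]
    beta <- as.numeric(stats::coef(cv, s = lambda_rule))
    if (all(beta == 0) && lambda_rule == "lambda.1se") {
      # the 1-SE rule can empty the model in small samples; fall back to
      # the minimum-deviance lambda before giving up
      warning("lambda.1se selected an empty model; falling back to lambda.min")
      lambda <- cv$lambda.min
      beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
    }
  } else {
    m <- glmnet::glmnet(x, y, family = "cox", lambda = lambda)
    beta <- as.numeric(stats::coef(m))
  }
  names(beta) <- feats
  sel <- beta[beta != 0]
  if (length(sel) == 0L)
    stop("all LASSO coefficients are zero at the selected lambda; ",
         "supply a finer/smaller lambda grid or stronger features")
  list(selected_features = names(sel), coefficients = sel,
       lambda = lambda, seed = as.integer(seed))
}

#' Fit a radiomic signature on the primary cohort
#'
#' Runs the full coarse-to-fine selection — univariate Cox screen, top-
#' fraction/alpha coarse filter, greedy correlation pruning, LASSO-Cox — on
#' the primary cohort and returns the fitted signature: selected features,
#' penalised Cox coefficients, the primary-cohort normalisation statistics,
#' and the primary-cohort median score as the risk-group cutoff (reused
#' verbatim on validation cohorts).
#'
#' @param features Primary-cohort feature table (data frame with
#'   `patient_id`).
#' @param records Primary-cohort survival records (`patient_id`,
#'   `time_months`, `event`); matched to `features` by `patient_id`.
#' @param fraction,alpha Coarse-filter parameters (defaults 0.20 and 0.1).
#' @param cor_cutoff Correlation-pruning threshold (default 0.6).
#' @param n_folds LASSO cross-validation folds (default 10).
#' @param top_mode Coarse-filter interpretation, see [coarse_filter()].
#' @param lambda_rule Penalty selection rule, see [fit_lasso_cox()].
#' @param seed Seed for the cross-validation fold assignment.
#' @return An object of class `radiomic_signature` with elements
#'   `selected_features`, `coefficients`, `normalization_stats`, `cutoff`,
#'   `lambda`, `seed`, and a `screening` list recording the nested survivor
#'   sets (`all`, `coarse`, `pruned`, `selected`) plus the univariate table.
#' @export
radiomic_signature <- function(features, records, fraction = 0.20,
                               alpha = 0.1, cor_cutoff = 0.6, n_folds = 10,
                               top_mode = "intersection",
                               lambda_rule = "lambda.1se", seed = 1L) {
  assert_that("patient_id" %in% names(features),
              "`features` must have a patient_id column")
  check_records(records, c("patient_id", "time_months", "event"))
  assert_that(setequal(features$patient_id, records$patient_id),
              "features and records must cover the same patients")
  records <- records[match(features$patient_id, records$patient_id), ]

  norm <- normalize_features(features)
  stats_ <- attr(norm, "stats")
  screen <- univariate_cox_screen(norm, records)
  coarse <- coarse_filter(screen, fraction = fraction, alpha = alpha,
                          mode = top_mode)
  assert_that(length(coarse) > 0,
              "coarse filter removed every feature (no p < alpha survivors)")
  pruned <- correlation_prune(norm[c("patient_id", coarse)],
                              cutoff = cor_cutoff)
  lasso <- fit_lasso_cox(norm[c("patient_id", pruned)], records,
                         n_folds = n_folds, seed = seed,
                         lambda_rule = lambda_rule)
  sel <- lasso$selected_features

  model <- structure(list(
    selected_features = sel,
    coefficients = lasso$coefficients,
    normalization_stats = list(mean = stats_$mean[sel], sd = stats_$sd[sel]),
    cutoff = NA_real_,
    lambda = lasso$lambda,
    seed = as.integer(seed),
    parameters = list(fraction = fraction, alpha = alpha,
                      cor_cutoff = cor_cutoff, n_folds = n_folds,
                      top_mode = top_mode, lambda_rule = lambda_rule),
    screening = list(all = screen$feature, coarse = coarse, pruned = pruned,
                     selected = sel, univariate = screen)),
    class = "radiomic_signature")
  model$cutoff <- stats::median(score(model, features))
  model
}

#' Signature score (penalised linear predictor)
#'
#' `score = sum(beta_j * (x_j - mean_j) / sd_j)` over the selected features,
#' using the stored primary-cohort normalisation statistics.
#'
#' @param model A [radiomic_signature].
#' @param feature_table Raw (un-normalised) feature table containing all
#'   selected features.
#' @return Named numeric vector of per-patient scores.
#' @export
score <- function(model, feature_table) {
  assert_that(inherits(model, "radiomic_signature"),
              "`model` must be a radiomic_signature")
  missing <- setdiff(model$selected_features, names(feature_table))
  assert_that(length(missing) == 0L,
              paste("feature table is missing:",
                    paste(missing, collapse = ", ")))
  st <- model$normalization_stats
  x <- as.matrix(feature_table[model$selected_features])
  z <- sweep(sweep(x, 2L, st$mean[model$selected_features], `-`),
             2L, st$sd[model$selected_features], `/`)
  s <- as.vector(z %*% model$coefficients[model$selected_features])
  assert_that(all(is.finite(s)), "non-finite signature score")
  if (!is.null(feature_table$patient_id)) names(s) <- feature_table$patient_id
  s
}

#' Stratify patients at the primary-cohort median cutoff
#'
#' High-risk iff `score > cutoff` (ties go to low risk); the cutoff is the
#' primary-cohort median stored in the model and reused verbatim for every
#' validation cohort.
#'
#' @param model A fitted [radiomic_signature] (with a cutoff).
#' @param scores Numeric vector of signature scores.
#' @return Factor with levels `low`, `high`.
#' @export
stratify <- function(model, scores) {
  assert_that(inherits(model, "radiomic_signature"),
              "`model` must be a radiomic_signature")
  assert_that(is.finite(model$cutoff),
              "model has no cutoff (fit on a primary cohort first)")
  factor(ifelse(scores > model$cutoff, "high", "low"),
         levels = c("low", "high"))
}

#' @export
print.radiomic_signature <- function(x, ...) {
  cat("Radiomic signature (LASSO-Cox)\n")
  cat(sprintf("  %d selected feature(s), lambda = %.5g, cutoff = %.5g\n",
              length(x$selected_features), x$lambda, x$cutoff))
  for (f in x$selected_features)
    cat(sprintf("    %+.4f  %s\n", x$coefficients[[f]], f))
  invisible(x)
}

#' @export
summary.radiomic_signature <- function(object, ...) {
  s <- object$screening
  cat("Coarse-to-fine selection\n")
  cat(sprintf("  screened:          %5d features\n", length(s$all)))
  cat(sprintf("  coarse filter:     %5d (top %.0f%%, p < %.2g)\n",
              length(s$coarse), 100 * object$parameters$fraction,
              object$parameters$alpha))
  cat(sprintf("  correlation prune: %5d (|r| <= %.2g)\n", length(s$pruned),
              object$parameters$cor_cutoff))
  cat(sprintf("  LASSO-Cox:         %5d selected\n", length(s$selected)))
  print(object)
  invisible(object)
}

#' @export
coef.radiomic_signature <- function(object, ...) object$coefficients

#' Predict method for radiomic signatures
#'
#' @param object A [radiomic_signature].
#' @param newdata Raw feature table.
#' @param type `"score"` for the continuous signature, `"group"` for the
#'   median-cutoff risk group.
#' @param ... Unused.
#' @return Numeric scores or a `low`/`high` factor.
#' @export
predict.radiomic_signature <- function(object, newdata,
                                       type = c("score", "group"), ...) {
  type <- match.arg(type)
  s <- score(object, newdata)
  if (type == "score") s else stratify(object, s)
}

#' Plot the signature coefficients
#'
#' @param x A [radiomic_signature].
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.radiomic_signature <- function(x, ...) {
  graphics::barplot(x$coefficients, horiz = TRUE, las = 1,
                    xlab = "LASSO-Cox coefficient", ...)
  invisible(x)
}

#' Serialise / reload a fitted signature
#'
#' Structured-text (JSON) round trip preserving features, coefficients,
#' normalisation statistics, cutoff, lambda and seed exactly.
#'
#' @param model A [radiomic_signature].
#' @param path Output path.
#' @return `path` invisibly; `read_signature()` returns the model.
#' @export
write_signature <- function(model, path) {
  obj <- list(selected_features = model$selected_features,
              coefficients = as.list(model$coefficients),
              normalization_mean = as.list(model$normalization_stats$mean),
              normalization_sd = as.list(model$normalization_stats$sd),
              cutoff = model$cutoff, lambda = model$lambda,
              seed = model$seed, parameters = model$parameters)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(selected_features = obj$selected_features,
                 coefficients = unlist(obj$coefficients),
                 normalization_stats = list(
                   mean = unlist(obj$normalization_mean),
                   sd = unlist(obj$normalization_sd)),
                 cutoff = obj$cutoff, lambda = obj$lambda,
                 seed = obj$seed, parameters = obj$parameters,
                 screening = NULL),
            class = "radiomic_signature")
}
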