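test_that("normalization fits on primary and reuses stored stats elsewhere", {
  set.seed(61)
  prim <- data.frame(patient_id = sprintf("p%d", 1:50),
                     f1 = rnorm(50, 10, 2), f2 = runif(50),
                     stringsAsFactors = FALSE)
  np <- normalize_features(prim)
  expect_lt(abs(mean(np$f1)), 1e-9)
  expect_lt(abs(sd(np$f1) - 1), 1e-9)

  st <- attr(np, "stats")
  valid <- data.frame(patient_id = sprintf("v%d", 1:30),
                      f1 = rnorm(30, 14, 2), f2 = runif(30),
                      stringsAsFactors = FALSE)
  nv <- normalize_features(valid, stats = st)
  # shifted cohort keeps its shift under the primary stats...
  expect_gt(mean(nv$f1), 1)
  # ...which is detectably different from re-normalising by itself
  expect_gt(abs(mean(nv$f1) - mean(normalize_features(valid)$f1)), 0.5)

  const <- prim; const$f1 <- 1
  expect_error(normalize_features(const), "constant")
  expect_error(normalize_features(data.frame(patient_id = "a", f3 = 1),
                                  stats = st), "absent")
})

test_that("univariate screen flags true signal and behaves under the null", {
  model <- cohort_model(baseline_rate = 0.02)
  set.seed(62)
  z <- rnorm(300)
  s <- simulate_survival(1.2 * z, model, seed = 62)
  s$patient_id <- seq_len(300)
  feats <- data.frame(patient_id = seq_len(300), risk = z,
                      noise = rnorm(300))
  res <- univariate_cox_screen(feats, s)
  expect_lt(res$p[res$feature == "risk"], 1e-3)
  expect_gt(res$p[res$feature == "noise"], 0.001)

  feats$flat <- 1
  expect_warning(res2 <- univariate_cox_screen(feats, s), "failed")
  expect_equal(res2$p[res2$feature == "flat"], 1)
})

test_that("univariate screen p-values are uniform under the null", {
  model <- cohort_model(baseline_rate = 0.02, censor_rate = 0.005)
  ps <- vapply(1:400, function(i) {
    set.seed(1000 + i)
    x <- rnorm(60)
    s <- simulate_survival(rep(0, 60), model, seed = 2000 + i)
    univariate_cox_screen(data.frame(patient_id = 1:60, x = x), s)$p
  }, 0)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("coarse filter implements the ranked top-fraction with p < alpha rule", {
  p <- setNames(seq(0.01, 0.10, by = 0.01), paste0("f", 1:10))
  expect_equal(coarse_filter(p, fraction = 0.2, alpha = 0.1),
               c("f1", "f2"))
  expect_length(coarse_filter(setNames(rep(0.2, 5), paste0("g", 1:5))), 0)
  # 1240 features cap at ceiling(0.2 * 1240) = 248
  set.seed(63)
  p_big <- setNames(runif(1240, 0, 0.05), paste0("h", 1:1240))
  expect_length(coarse_filter(p_big), 248)
  # subset mode: top 20% of the p < alpha survivors
  p2 <- setNames(c(0.01, 0.02, 0.05, 0.08, 0.09, 0.5, 0.7, 0.9, 0.95, 0.99),
                 paste0("k", 1:10))
  expect_equal(coarse_filter(p2, mode = "subset"), "k1")
})

test_that("correlation pruning follows the greedy mean-absolute-correlation rule", {
  set.seed(64)
  n <- 100
  a <- rnorm(n)
  tab <- data.frame(a = a, b = a + rnorm(n, sd = 0.1),
                    c = rnorm(n), d = a + rnorm(n, sd = 0.5))
  # oracle: step-by-step simulation of the documented greedy procedure
  greedy_oracle <- function(df, cutoff = 0.6) {
    keep <- names(df)
    repeat {
      r <- abs(cor(df[keep])); diag(r) <- 0
      if (max(r) <= cutoff) break
      hit <- which(r == max(r), arr.ind = TRUE)
      prs <- unique(t(apply(cbind(rownames(r)[hit[, 1]],
                                  colnames(r)[hit[, 2]]), 1, sort)))
      prs <- prs[order(prs[, 1], prs[, 2]), , drop = FALSE]
      pair <- prs[1, ]
      mac <- rowMeans(r)[pair]
      drop_ <- if (mac[1] > mac[2]) pair[1]
               else if (mac[2] > mac[1]) pair[2]
               else pair[which.max(match(pair, names(df)))]
      keep <- setdiff(keep, drop_)
    }
    keep
  }
  expect_equal(correlation_prune(tab), greedy_oracle(tab))

  # perfectly correlated pair: exactly one survives
  two <- data.frame(x = a, y = 2 * a + 3)
  expect_length(correlation_prune(two), 1)
})

test_that("pruned sets never exceed the correlation bound (property sweep)", {
  set.seed(65)
  for (i in 1:100) {
    p <- sample(3:8, 1); n <- sample(10:40, 1)
    base <- matrix(rnorm(n * 3), n, 3)
    tab <- as.data.frame(base[, sample(1:3, p, replace = TRUE)] +
                           matrix(rnorm(n * p, sd = runif(1, 0.05, 2)), n, p))
    names(tab) <- paste0("v", seq_len(p))
    keep <- correlation_prune(tab, cutoff = 0.6)
    expect_gte(length(keep), 1)
    if (length(keep) > 1) {
      r <- abs(cor(tab[keep])); diag(r) <- 0
      expect_lte(max(r), 0.6 + 1e-12)
    }
  }
})

test_that("full shrinkage at huge lambda raises the documented error", {
  model <- cohort_model(baseline_rate = 0.02)
  set.seed(66)
  x <- matrix(rnorm(100 * 5), 100, 5)
  s <- simulate_survival(x[, 1], model, seed = 66)
  tab <- as.data.frame(x); names(tab) <- paste0("f", 1:5)
  expect_error(fit_lasso_cox(tab, s, seed = 1, lambda = 1e4),
               "all LASSO coefficients are zero")
  # with a sensible penalty the informative feature is picked up
  fit <- fit_lasso_cox(tab, s, seed = 1)
  expect_true("f1" %in% fit$selected_features)
})

test_that("signature scoring is the stored-normalisation linear predictor", {
  model <- structure(list(
    selected_features = c("f1", "f2"),
    coefficients = c(f1 = 0.5, f2 = -2),
    normalization_stats = list(mean = c(f1 = 10, f2 = 1),
                               sd = c(f1 = 2, f2 = 0.5)),
    cutoff = 0, lambda = 0.1, seed = 1L), class = "radiomic_signature")
  tab <- data.frame(patient_id = c("a", "b"), f1 = c(10, 14), f2 = c(1, 2),
                    stringsAsFactors = FALSE)
  s <- score(model, tab)
  expect_equal(unname(s), c(0.5 * 0 - 2 * 0, 0.5 * 2 - 2 * 2))
  expect_named(s, c("a", "b"))
  expect_error(score(model, tab[, 1:2]), "missing")
  # affine equivariance in one feature: adding one sd adds one beta
  tab2 <- tab; tab2$f1 <- tab2$f1 + 2
  expect_equal(unname(score(model, tab2) - s), c(0.5, 0.5))
})

test_that("median stratification splits and ports the cutoff", {
  model <- structure(list(
    selected_features = "f", coefficients = c(f = 1),
    normalization_stats = list(mean = c(f = 0), sd = c(f = 1)),
    cutoff = 3, lambda = 0, seed = 1L), class = "radiomic_signature")
  g <- stratify(model, c(1, 2, 3, 4, 5))
  expect_equal(as.character(g), c("low", "low", "low", "high", "high"))
  # shifting scores moves patients without moving the cutoff
  g2 <- stratify(model, c(1, 2, 3, 4, 5) + 2)
  expect_equal(sum(g2 == "high"), 4)
  model$cutoff <- NA_real_
  expect_error(stratify(model, 1:3), "cutoff")
})

test_that("end-to-end fit recovers planted features and orders risk", {
  model <- cohort_model(baseline_rate = 0.02, censor_rate = 0.005)
  n <- 400
  ok_sel <- 0; ok_cor <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    set.seed(7000 + r)
    x_true <- matrix(rnorm(n * 3), n, 3)
    x_noise <- matrix(rnorm(n * 100), n, 100)
    tab <- data.frame(patient_id = sprintf("p%d", 1:n), x_true, x_noise,
                      stringsAsFactors = FALSE)
    names(tab)[-1] <- c(paste0("true", 1:3), paste0("noise", 1:100))
    lp <- x_true %*% c(1, -1, 1)
    s <- simulate_survival(as.vector(lp), model, seed = 7100 + r)
    s$patient_id <- tab$patient_id
    fit <- fit_lasso_cox(normalize_features(tab), s, seed = r)
    sel <- fit$selected_features
    n_true <- sum(paste0("true", 1:3) %in% sel)
    n_fp <- sum(startsWith(sel, "noise"))
    if (n_true == 3 && n_fp <= 10) ok_sel <- ok_sel + 1
    sc <- as.matrix(normalize_features(tab)[sel]) %*% fit$coefficients
    if (abs(cor(sc, lp, method = "spearman")) >= 0.7) ok_cor <- ok_cor + 1
  }
  expect_gte(ok_sel / reps, 0.9)
  expect_gte(ok_cor / reps, 0.9)
})

test_that("the full fitter keeps stages nested and is seed-deterministic", {
  model <- cohort_model(baseline_rate = 0.03, censor_rate = 0.005)
  n <- 150
  set.seed(68)
  x <- matrix(rnorm(n * 30), n, 30)
  x[, 2] <- x[, 1] + rnorm(n, sd = 0.2)  # a correlated pair
  tab <- data.frame(patient_id = sprintf("p%d", 1:n), x,
                    stringsAsFactors = FALSE)
  names(tab)[-1] <- paste0("f", 1:30)
  s <- simulate_survival(x[, 1] - x[, 3], model, seed = 68)
  s$patient_id <- tab$patient_id
  rec <- s[, c("patient_id", "time_months", "event")]
  fit1 <- radiomic_signature(tab, rec, seed = 3)
  fit2 <- radiomic_signature(tab, rec, seed = 3)
  expect_identical(fit1$coefficients, fit2$coefficients)
  expect_identical(fit1$cutoff, fit2$cutoff)
  scr <- fit1$screening
  expect_true(all(scr$selected %in% scr$pruned))
  expect_true(all(scr$pruned %in% scr$coarse))
  expect_true(all(scr$coarse %in% scr$all))
  # median cutoff splits the primary cohort near-evenly
  g <- stratify(fit1, score(fit1, tab))
  expect_lte(abs(sum(g == "high") - sum(g == "low")), 1)
})

test_that("signatures survive a serialisation round trip", {
  model <- structure(list(
    selected_features = c("a|b|c|d", "e|f|g|h"),
    coefficients = c(`a|b|c|d` = 0.123456789, `e|f|g|h` = -1.5),
    normalization_stats = list(mean = c(`a|b|c|d` = 1, `e|f|g|h` = 2),
                               sd = c(`a|b|c|d` = 3, `e|f|g|h` = 4)),
    cutoff = 0.25, lambda = 0.05, seed = 9L,
    parameters = list(fraction = 0.2, alpha = 0.1, cor_cutoff = 0.6,
                      n_folds = 10, top_mode = "intersection")),
    class = "radiomic_signature")
  f <- withr::local_tempfile(fileext = ".json")
  write_signature(model, f)
  back <- read_signature(f)
  expect_equal(back$coefficients, model$coefficients)
  expect_equal(back$normalization_stats, model$normalization_stats)
  expect_equal(back$cutoff, model$cutoff)
  tab <- data.frame(patient_id = "p", `a|b|c|d` = 2, `e|f|g|h` = 1,
                    check.names = FALSE, stringsAsFactors = FALSE)
  expect_equal(score(back, tab), score(model, tab))
})
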