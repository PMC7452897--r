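test_that("Kaplan-Meier matches hand-worked product-limit examples", {
  # events at 1, 2, 3, 4: empirical survival
  km <- km_estimate(records_of(1:4, rep(1, 4)))
  expect_equal(km_survival_at(km, 2.5), 0.5)
  expect_equal(km_survival_at(km, 0.5), 1)
  expect_equal(km_survival_at(km, 4), 0)

  # censoring keeps subjects in earlier risk sets
  km2 <- km_estimate(records_of(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(km_survival_at(km2, 1), 2 / 3)
  expect_equal(km_survival_at(km2, 3), 0)

  # all censored: flat at 1
  km3 <- km_estimate(records_of(c(2, 5, 9), c(0, 0, 0)))
  expect_equal(km_survival_at(km3, 9), 1)
})

test_that("Kaplan-Meier equals brute-force risk-set counting under censoring", {
  set.seed(71)
  t_ <- round(rexp(80, 0.1), 1) + 0.1
  e <- rbinom(80, 1, 0.6)
  km <- km_estimate(records_of(t_, e))
  for (at in c(2, 5, 10, 20))
    expect_equal(km_survival_at(km, at), oracle_km(t_, e, at),
                 tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
})

test_that("log-rank matches the observed-minus-expected oracle and is symmetric", {
  a <- records_of(c(1, 3, 5), c(1, 1, 0))
  b <- records_of(c(2, 4, 6), c(1, 0, 1))
  lr <- logrank_test(a, b)
  orc <- oracle_logrank(a$time_months, a$event, b$time_months, b$event)
  expect_equal(lr$statistic, orc$statistic, tolerance = 1e-9)
  expect_equal(lr$p, orc$p, tolerance = 1e-9)
  lr_swap <- logrank_test(b, a)
  expect_equal(lr$statistic, lr_swap$statistic, tolerance = 1e-12)

  same <- records_of(c(1, 2, 3), c(1, 1, 1))
  lr_same <- logrank_test(same, same)
  expect_equal(lr_same$statistic, 0, tolerance = 1e-9)
  expect_equal(lr_same$p, 1, tolerance = 1e-9)

  none <- records_of(c(1, 2), c(0, 0))
  expect_warning(lr0 <- logrank_test(none, none), "no events")
  expect_equal(lr0$p, 1)
})

test_that("Cox fit recovers a log-2 hazard ratio with calibrated coverage", {
  covered <- 0; reps <- 100
  for (r in seq_len(reps)) {
    s <- sim_exp_records(400, beta = log(2), rate = 0.02, censor = 0.005,
                         admin = 120, seed = 8000 + r)
    tab <- fit_cox(data.frame(x = s$x), s)$table
    if (tab$hr_lower[1] <= 2 && 2 <= tab$hr_upper[1]) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.93)
  s_big <- sim_exp_records(2000, beta = log(2), rate = 0.02, seed = 8999)
  hr <- fit_cox(data.frame(x = s_big$x), s_big)$table$hr[1]
  expect_gt(hr, 1.8); expect_lt(hr, 2.2)
})

test_that("Cox score equation solution matches a brute-force 4-patient oracle", {
  # single binary covariate, no ties: maximise the partial likelihood directly
  rec <- records_of(c(1, 2, 3, 4), c(1, 1, 1, 0))
  x <- c(1, 0, 1, 0)
  loglik <- function(b) {
    ll <- 0
    for (i in which(rec$event == 1)) {
      rs <- rec$time_months >= rec$time_months[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[rs])))
    }
    ll
  }
  b_oracle <- optimize(loglik, c(-10, 10), maximum = TRUE)$maximum
  fit <- fit_cox(data.frame(x = x), rec)
  expect_equal(unname(fit$coefficients), b_oracle, tolerance = 1e-4)
  # HR/CI consistency with beta and covariance
  expect_equal(fit$table$hr[1], exp(fit$table$coef[1]), tolerance = 1e-12)
  expect_equal(fit$table$hr_upper[1],
               exp(fit$table$coef[1] + 1.96 * fit$table$se[1]),
               tolerance = 1e-12)
})

test_that("Cox fit rejects constant covariates", {
  rec <- records_of(1:10, rep(1, 10))
  expect_error(fit_cox(data.frame(x = rep(1, 10)), rec), "constant")
})

test_that("time-dependent AUC is 1 for a perfect marker, 0.5 for noise", {
  set.seed(72)
  t_ <- rexp(300, 0.05) + 0.01
  rec <- records_of(t_, rep(1, 300))
  auc <- time_dependent_auc(-t_, rec, horizons = c(12, 24))
  expect_equal(unname(auc), c(1, 1), tolerance = 1e-12)
  aun <- time_dependent_auc(rnorm(300), rec, horizons = c(12, 24))
  expect_lt(max(abs(aun - 0.5)), 0.08)
  expect_error(time_dependent_auc(-t_, rec, horizons = max(t_) + 1),
               "exceeds")
})

test_that("uncensored AUC equals case-control pair counting", {
  set.seed(73)
  t_ <- rexp(120, 0.04) + 0.01
  m <- -t_ + rnorm(120, sd = 5)
  rec <- records_of(t_, rep(1, 120))
  for (h in c(10, 25)) {
    expect_equal(unname(time_dependent_auc(m, rec, horizons = h)),
                 oracle_auc_uncensored(m, t_, h), tolerance = 1e-9)
  }
})

test_that("AUC and C-index are invariant under monotone marker transforms", {
  set.seed(74)
  t_ <- rexp(150, 0.05) + 0.01
  e <- rbinom(150, 1, 0.7)
  m <- rnorm(150)
  rec <- records_of(t_, e)
  expect_equal(time_dependent_auc(m, rec, 12),
               time_dependent_auc(exp(2 * m) + 3, rec, 12),
               tolerance = 1e-12)
  expect_equal(harrell_cindex(m, rec)$c,
               harrell_cindex(exp(2 * m) + 3, rec)$c, tolerance = 1e-12)
})

test_that("C-index matches exhaustive pair enumeration and reference code", {
  rec3 <- records_of(c(2, 5, 9), c(1, 1, 1))
  m3 <- c(3, 1, 2)  # one discordant pair
  res <- harrell_cindex(m3, rec3)
  expect_equal(res$c, oracle_cindex(m3, rec3$time_months, rec3$event))
  expect_equal(res$n_pairs, 3)

  set.seed(75)
  t_ <- rexp(60, 0.05) + 0.01
  e <- rbinom(60, 1, 0.6)
  m <- rnorm(60)
  rec <- records_of(t_, e)
  mine <- harrell_cindex(m, rec)
  expect_equal(mine$c, oracle_cindex(m, t_, e), tolerance = 1e-12)
  # independent implementation: survival::concordance (marker sign flipped:
  # concordance() treats larger x as longer survival)
  ref <- survival::concordance(survival::Surv(t_, e) ~ m, reverse = TRUE)
  expect_equal(mine$c, unname(ref$concordance), tolerance = 1e-12)

  perfect <- harrell_cindex(-t_, records_of(t_, rep(1, 60)))
  expect_equal(perfect$c, 1)
  set.seed(76)
  null_c <- harrell_cindex(rnorm(500),
                           records_of(rexp(500, 0.05), rbinom(500, 1, 0.7)))
  expect_lt(abs(null_c$c - 0.5), 0.05)
})

test_that("baseline comparison routes tests by type, normality and cell counts", {
  set.seed(77)
  a <- data.frame(age = rnorm(60, 55, 10), cea = rexp(60),
                  stage = sample(c("II", "III"), 60, TRUE),
                  stringsAsFactors = FALSE)
  res_same <- compare_baselines(a, a)
  expect_true(all(res_same$p > 0.99))
  expect_equal(res_same$test[res_same$variable == "age"], "t")
  expect_equal(res_same$test[res_same$variable == "cea"], "mann-whitney")

  # small counts route to Fisher
  s1 <- data.frame(g = c(rep("x", 3), rep("y", 7)), stringsAsFactors = FALSE)
  s2 <- data.frame(g = c(rep("x", 8), rep("y", 2)), stringsAsFactors = FALSE)
  expect_equal(compare_baselines(s1, s2)$test, "fisher")

  # 2x2 chi-square equals the closed form on (30, 70) vs (50, 50)
  b1 <- data.frame(g = c(rep("x", 30), rep("y", 70)),
                   stringsAsFactors = FALSE)
  b2 <- data.frame(g = c(rep("x", 50), rep("y", 50)),
                   stringsAsFactors = FALSE)
  res <- compare_baselines(b1, b2)
  tab <- rbind(c(30, 70), c(50, 50))
  e <- outer(rowSums(tab), colSums(tab)) / 200
  chi <- sum((tab - e)^2 / e)
  expect_equal(res$test, "chi-square")
  expect_equal(res$p, pchisq(chi, 1, lower.tail = FALSE), tolerance = 1e-12)
})
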