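test_that("a single binary covariate maps to point values 0 and 100", {
  s <- sim_exp_records(120, beta = 0.8, rate = 0.03, seed = 81)
  nom <- build_nomogram(data.frame(x = s$x), s)
  pts <- nomogram_points(nom)
  expect_setequal(round(unique(pts[, "x"]), 9), c(0, 100))
  expect_equal(pts[, "x"], pts[, "total"])
})

test_that("nomogram predictions reproduce the Cox model exactly", {
  set.seed(82)
  s <- sim_exp_records(150, beta = log(2), rate = 0.03, censor = 0.01,
                       admin = 100, seed = 82)
  cov <- data.frame(x = s$x, z = rnorm(150))
  nom <- build_nomogram(cov, s)
  # back out the linear predictor from total points and compare predictions
  pts <- nomogram_points(nom, cov)
  lp_from_points <- unname(pts[, "total"] / nom$points_scale +
                             sum(nom$point_ref))
  lp_direct <- unname(predict(nom$cox$fit, type = "lp", reference = "zero"))
  expect_equal(lp_from_points, lp_direct, tolerance = 1e-9)
  p1 <- predict_dmfs(nom, cov, horizon = 24)
  h0 <- nom$basehaz$hazard[max(which(nom$basehaz$time <= 24))]
  expect_equal(p1, exp(-h0)^exp(lp_direct), tolerance = 1e-9)
})

test_that("predicted survival is monotone in horizon and linear predictor", {
  s <- sim_exp_records(200, beta = 1, rate = 0.03, seed = 83)
  nom <- build_nomogram(data.frame(x = s$x), s)
  p12 <- predict_dmfs(nom, horizon = 12)
  p24 <- predict_dmfs(nom, horizon = 24)
  expect_true(all(p24 <= p12 + 1e-12))
  expect_true(all(p12 >= 0 & p12 <= 1))
  # lp = 0 recovers the baseline itself
  p0 <- predict_dmfs(nom, data.frame(x = 0), horizon = 24)
  h0 <- nom$basehaz$hazard[max(which(nom$basehaz$time <= 24))]
  expect_equal(p0, exp(-h0), tolerance = 1e-12)
})

test_that("Breslow baseline matches a hand computation on 5 patients", {
  # no ties, single binary covariate
  rec <- records_of(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 0))
  x <- c(1, 1, 0, 1, 0)
  nom <- build_nomogram(data.frame(x = x), rec)
  b <- unname(nom$cox$coefficients)
  r <- exp(b * x)
  # Breslow increments at event times 1, 3, 4 over the at-risk sums
  h0 <- cumsum(c(1 / sum(r[1:5]), 1 / sum(r[3:5]), 1 / sum(r[4:5])))
  expect_equal(basehaz_at <- vapply(c(1, 3, 4), function(t)
    nom$basehaz$hazard[max(which(nom$basehaz$time <= t))], 0),
    h0, tolerance = 1e-9)
})

test_that("calibration is tight when predictions equal the true survival", {
  set.seed(84)
  n <- 2000
  rate <- 0.02 * exp(rnorm(n))
  t_ <- rexp(n, rate)
  rec <- records_of(pmin(t_, 80), as.integer(t_ <= 80))
  pred <- exp(-rate * 36)  # true 36-month survival
  cal <- calibration_curve(pred, rec, horizon = 36, n_groups = 5)
  expect_equal(nrow(cal), 5)
  expect_lt(mean(abs(cal$predicted - cal$observed)), 0.05)
  # group KM estimates bracket sensible probabilities
  expect_true(all(cal$observed >= 0 & cal$observed <= 1))
  expect_warning(one <- calibration_curve(rep(0.5, n), rec, horizon = 36),
                 "degenerate")
  expect_equal(nrow(one), 1)
})

test_that("net benefit matches closed forms and confusion-matrix counting", {
  set.seed(85)
  n <- 400
  event <- rbinom(n, 1, 0.3)
  # uncensored records: event at 10, survivors administratively at 100
  rec <- records_of(ifelse(event == 1, 10, 100), event)
  pred <- plogis(qlogis(0.3) + 2 * event + rnorm(n))
  prev <- mean(event)
  dca <- decision_curve(pred, rec, horizon = 36,
                        thresholds = c(0.1, 0.2, 0.4))
  for (k in seq_len(nrow(dca))) {
    pt <- dca$threshold[k]
    expect_equal(dca$treat_all[k], prev - (1 - prev) * pt / (1 - pt),
                 tolerance = 1e-9)
    expect_equal(dca$net_benefit[k], oracle_net_benefit(pred, event, pt),
                 tolerance = 1e-9)
  }
  expect_true(all(dca$treat_none == 0))
  # perfect predictor: NB equals prevalence at every threshold
  dca_p <- decision_curve(as.numeric(event), rec, horizon = 36,
                          thresholds = c(0.1, 0.3, 0.5))
  expect_equal(dca_p$net_benefit, rep(prev, 3), tolerance = 1e-9)
  expect_error(decision_curve(pred, rec, 36, thresholds = 1), "inside")
})

test_that("NRI/IDI vanish for identical models and match hand counting", {
  set.seed(86)
  n <- 500
  event <- rbinom(n, 1, 0.4)
  rec <- records_of(ifelse(event == 1, 12, 90), event)
  old <- runif(n); new <- plogis(qlogis(pmin(pmax(old, 0.01), 0.99)) +
                                   1.5 * event + rnorm(n, sd = 0.5))
  expect_warning(z <- compute_nri(old, old, rec, 36), "no reclassification")
  expect_equal(z$nri, 0)
  expect_equal(compute_idi(old, old, rec, 36)$idi, 0)

  nri <- compute_nri(old, new, rec, 36)
  expect_equal(nri$nri, oracle_nri(old, new, event), tolerance = 1e-9)
  idi <- compute_idi(old, new, rec, 36)
  expect_equal(idi$idi, oracle_idi(old, new, event), tolerance = 1e-9)

  # antisymmetry under swapping the models
  expect_equal(compute_nri(new, old, rec, 36)$nri, -nri$nri,
               tolerance = 1e-9)
  expect_equal(compute_idi(new, old, rec, 36)$idi, -idi$idi,
               tolerance = 1e-9)

  # 4-subject toy: up-mover event, down-mover non-event
  rec4 <- records_of(c(5, 50, 50, 50), c(1, 0, 0, 0))
  old4 <- c(0.2, 0.2, 0.3, 0.3); new4 <- c(0.5, 0.2, 0.1, 0.3)
  nri4 <- compute_nri(old4, new4, rec4, 36)
  expect_equal(nri4$nri, oracle_nri(old4, new4, c(1, 0, 0, 0)),
               tolerance = 1e-9)
})

test_that("informative markers raise NRI; pure noise leaves IDI near 0", {
  set.seed(87)
  nri_pos <- 0
  for (r in 1:20) {
    n <- 1000
    z <- rnorm(n)
    rate <- 0.02 * exp(z)
    t_ <- rexp(n, rate)
    rec <- records_of(pmin(t_, 80), as.integer(t_ <= 80))
    old <- runif(n)
    new <- 1 - exp(-rate * 36)
    if (compute_nri(old, new, rec, 36)$nri > 0) nri_pos <- nri_pos + 1
  }
  expect_gte(nri_pos / 20, 0.95)

  n <- 2000
  event <- rbinom(n, 1, 0.3)
  rec <- records_of(ifelse(event == 1, 12, 90), event)
  base <- plogis(-1 + 1.2 * event + rnorm(n))
  noisy <- plogis(qlogis(base) + rnorm(n, sd = 0.1))
  expect_lt(abs(compute_idi(base, noisy, rec, 36)$idi), 0.02)
})
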