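test_that("phantoms are bit-identical under a fixed seed", {
  spec <- tiny_spec()
  a <- generate_phantom_pair(spec, 0.7, seed = 99)
  b <- generate_phantom_pair(spec, 0.7, seed = 99)
  expect_identical(a$t2w$voxels, b$t2w$voxels)
  expect_identical(a$dwi_b0$voxels, b$dwi_b0$voxels)
  expect_identical(a$dwi_b1000$voxels, b$dwi_b1000$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  c_ <- generate_phantom_pair(spec, 0.7, seed = 100)
  expect_false(identical(a$t2w$voxels, c_$t2w$voxels))
})

test_that("DWI pair encodes a monoexponential ADC field", {
  spec <- tiny_spec()
  ph <- generate_phantom_pair(spec, 0.3, seed = 7)
  adc <- adc_from_dwi(ph$dwi_b0, ph$dwi_b1000)
  expect_true(all(adc$voxels > 0))
  # tumor diffusion restricted relative to background
  expect_lt(mean(adc$voxels[ph$mask$voxels]),
            mean(adc$voxels[!ph$mask$voxels]))
})

test_that("disabled heterogeneity link equalises texture across risks", {
  spec <- tiny_spec(heterogeneity_link = c(intercept = 0.4, slope = 0))
  v <- vapply(c(-2, 0, 2), function(r) {
    ph <- generate_phantom_pair(spec, r, seed = 123)
    var(ph$t2w$voxels[ph$mask$voxels])
  }, 0)
  expect_lt(max(v) / min(v), 1.5)  # sampling noise only
})

test_that("higher latent risk produces rougher tumor texture", {
  spec <- tiny_spec()
  var_at <- function(r, seeds) vapply(seeds, function(s) {
    ph <- generate_phantom_pair(spec, r, seed = s)
    var(ph$t2w$voxels[ph$mask$voxels])
  }, 0)
  v_lo <- var_at(-1, 1:50)
  v_hi <- var_at(1, 101:150)
  expect_lt(wilcox.test(v_lo, v_hi, alternative = "less")$p.value, 0.01)
})

test_that("tumors that cannot fit the grid are rejected", {
  expect_error(phantom_spec(grid_shape = c(8L, 8L, 8L), spacing_mm = c(1, 1, 1),
                            tumor_radius_range_mm = c(6, 8)),
               "too small")
})

test_that("mask perturbation preserves identity at 0 and overlap at 1", {
  m <- ball_mask(10, spacing = 1)
  expect_identical(perturb_mask(m, 0, seed = 1)$voxels, m$voxels)
  p <- perturb_mask(m, 1, seed = 2)
  inter <- sum(p$voxels & m$voxels)
  dice <- 2 * inter / (sum(p$voxels) + sum(m$voxels))
  expect_gte(dice, 0.8)
  expect_lt(abs(sum(p$voxels) - sum(m$voxels)) / sum(m$voxels), 0.3)
  expect_error(perturb_mask(m, 11, seed = 3), "radius")
})

test_that("exponential survival matches its closed-form median", {
  model <- cohort_model(baseline_rate = 0.02, censor_rate = 0,
                        admin_censor_months = 1e6)
  s <- simulate_survival(rep(0, 10000), model, seed = 5)
  expect_equal(sum(s$event), 10000)
  expect_lt(abs(median(s$time_months) - log(2) / 0.02), 1)
})

test_that("a log-2 hazard ratio is recovered by a Cox fit at n=2000", {
  model <- cohort_model(baseline_rate = 0.02, censor_rate = 0.01)
  set.seed(6)
  x <- rbinom(2000, 1, 0.5)
  s <- simulate_survival(log(2) * x, model, seed = 6)
  hr <- fit_cox(data.frame(x = x), s)$table$hr[1]
  expect_gt(hr, 1.8); expect_lt(hr, 2.2)
})

test_that("an immediate administrative cutoff censors everyone", {
  model <- cohort_model(admin_censor_months = 0.001)
  s <- simulate_survival(rep(0, 2000), model, seed = 7)
  expect_lt(mean(s$event), 0.01)
})

test_that("non-finite linear predictors are rejected", {
  model <- cohort_model()
  expect_error(simulate_survival(c(0, NA), model, seed = 1), "finite")
  expect_error(simulate_survival(c(0, Inf), model, seed = 1), "finite")
})

test_that("clinical covariates follow the specified marginals", {
  model <- cohort_model()
  cov <- simulate_clinical(model, "primary", 10000, seed = 8)
  expect_lt(abs(mean(cov$adjuvant_ct == "1") - 0.665), 0.02)
  expect_lt(abs(mean(cov$clinical_stage == "III") - 0.506), 0.02)
  # degenerate marginal: everyone one level
  marg <- model$covariate_marginals
  marg$primary$cea <- c("<5" = 1, ">=5" = 0)
  m2 <- cohort_model(covariate_marginals = marg)
  cov2 <- simulate_clinical(m2, "primary", 50, seed = 9)
  expect_true(all(cov2$cea == "<5"))
  expect_error(simulate_clinical(model, "nonexistent", 10, seed = 1),
               "unknown cohort")
})

test_that("invalid covariate frequencies are rejected", {
  marg <- cohort_model()$covariate_marginals
  marg$primary$cea <- c("<5" = 0.5, ">=5" = 0.4)
  expect_error(cohort_model(covariate_marginals = marg), "sum to 1")
})

test_that("the four default cohorts total 629 records with a stable manifest", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  model <- cohort_model()
  spec <- phantom_spec()
  r1 <- generate_cohort(model, spec, dir1, write_images = FALSE)
  r2 <- generate_cohort(model, spec, dir2, write_images = FALSE)
  expect_equal(nrow(r1$records), 629)
  expect_equal(as.vector(table(r1$records$cohort)[c("primary", "v1", "v2",
                                                    "v3")]),
               c(176, 154, 150, 149))
  expect_identical(unname(tools::md5sum(r1$manifest)),
                   unname(tools::md5sum(r2$manifest)))
  # ground truth is recoverable: Cox on the full data-generating model
  rec <- r1$records
  sc <- clinical_covariates(rec)
  tx <- as.numeric(as.character(rec$adjuvant_ct))
  cov <- data.frame(z = rec$latent_risk, sc,
                    neo = as.numeric(as.character(rec$neoadjuvant)),
                    tx = tx, tx_high = tx * (rec$latent_risk > 0))
  fit <- fit_cox(cov, rec)
  se_z <- fit$table$se[fit$table$covariate == "z"]
  expect_lt(abs(fit$coefficients[["z"]] - model$beta_risk), 2 * se_z)
  expect_gt(fit$coefficients[["tx_high"]], 0)
})

test_that("a positive planted interaction raises the treated hazard in high-risk", {
  model <- cohort_model(n_patients = c(primary = 2000L, v1 = 1L, v2 = 1L,
                                       v3 = 1L))
  set.seed(10)
  z <- rnorm(2000)
  tx <- rbinom(2000, 1, 0.5)
  lp <- model$beta_risk * z + model$beta_treatment * tx +
    model$beta_interaction * tx * (z > 0)
  s <- simulate_survival(lp, model, seed = 11)
  hr_in <- function(sel) fit_cox(data.frame(tx = tx[sel]),
                                 s[sel, ])$table$hr[1]
  expect_gt(hr_in(z > 0), hr_in(z <= 0))
})
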