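# Synthetic multi-cohort study generator: clinical covariates with
# realistic marginals, proportional-hazards DMFS outcomes driven by a latent
# risk, and a built-in chemotherapy-by-risk-group interaction.

.cohort_names <- c("primary", "v1", "v2", "v3")

#' Default per-cohort covariate marginals
#'
#' Category frequencies emulating a four-centre locally advanced rectal
#' cancer study (primary cohort plus three external validation cohorts).
#' @noRd
default_marginals <- function() {
  mk <- function(stage3, pt, pn, loc, cea_hi, neo, act) {
    list(clinical_stage = c("II" = 1 - stage3, "III" = stage3),
         pT = c("0" = pt[1], "1/2" = pt[2], "3/4" = pt[3]),
         pN = c("0" = pn[1], "1" = pn[2], "2" = pn[3]),
         location = c(">10" = loc[1], "5-10" = loc[2], "<5" = loc[3]),
         cea = c("<5" = 1 - cea_hi, ">=5" = cea_hi),
         neoadjuvant = c("0" = 1 - neo, "1" = neo),
         adjuvant_ct = c("0" = 1 - act, "1" = act))
  }
  list(
    primary = mk(0.506, c(0.023, 0.136, 0.841), c(0.455, 0.375, 0.170),
                 c(0.176, 0.369, 0.455), 0.381, 0.358, 0.665),
    v1 = mk(0.851, c(0.227, 0.195, 0.578), c(0.597, 0.279, 0.124),
            c(0.669, 0.325, 0.006), 0.474, 1.000, 0.331),
    v2 = mk(0.720, c(0.180, 0.173, 0.647), c(0.573, 0.273, 0.154),
            c(0.073, 0.540, 0.387), 0.240, 0.540, 0.820),
    v3 = mk(0.644, c(0.000, 0.174, 0.826), c(0.678, 0.161, 0.161),
            c(0.081, 0.624, 0.295), 0.342, 0.577, 0.772))
}

#' Specify the ground-truth cohort model
#'
#' Defines the data-generating process for a four-cohort synthetic study:
#' cohort sizes, log-hazard effects of the latent risk, clinical covariates,
#' adjuvant chemotherapy and its interaction with the high-risk group
#' (latent risk above its population median, 0), an exponential baseline
#' hazard, and independent exponential plus administrative censoring.
#'
#' The linear predictor of patient i is
#' `lp = beta_risk * z_i + sum(beta_clinical * x_i) + beta_treatment * tx_i +
#'  beta_interaction * tx_i * 1[z_i > 0]`, with `z_i ~ N(0, 1)` latent risk.
#'
#' @param n_patients Named integer vector of cohort sizes
#'   (`primary`, `v1`, `v2`, `v3`).
#' @param beta_risk Log-HR per unit latent risk.
#' @param beta_clinical Named log-HR vector for the ordinal scores of
#'   `pN` (0/1/2), `pT` (0/1/2 for 0, 1-2, 3-4), `clinical_stage` (II=0,
#'   III=1), `cea` (<5=0, >=5=1), `location` (>10=0, 5-10=1, <5=2),
#'   `neoadjuvant` (0/1).
#' @param beta_treatment Log-HR of adjuvant chemotherapy in the low-risk
#'   group.
#' @param beta_interaction Additional chemotherapy log-HR in the high-risk
#'   group.
#' @param baseline_rate Exponential baseline hazard (events/month).
#' @param censor_rate Exponential censoring hazard (events/month); 0 disables
#'   random censoring.
#' @param admin_censor_months Administrative cutoff (months).
#' @param covariate_marginals Per-cohort list of per-covariate category
#'   frequencies (each summing to 1).
#' @param seed Default seed used by [generate_cohort()].
#' @return An object of class `cohort_model`.
#' @export
cohort_model <- function(n_patients = c(primary = 176L, v1 = 154L,
                                        v2 = 150L, v3 = 149L),
                         beta_risk = 1.2,
                         beta_clinical = c(pN = 0.35, pT = 0.3,
                                           clinical_stage = 0.2, cea = 0.2,
                                           location = 0.15, neoadjuvant = 0),
                         beta_treatment = -0.3,
                         beta_interaction = 0.85,
                         baseline_rate = 0.004,
                         censor_rate = 0.008,
                         admin_censor_months = 60,
                         covariate_marginals = default_marginals(),
                         seed = 20260102L) {
  assert_that(all(.cohort_names %in% names(n_patients)),
              "`n_patients` must name cohorts primary, v1, v2, v3")
  assert_that(all(n_patients > 0), "cohort sizes must be positive")
  assert_that(baseline_rate > 0, "`baseline_rate` must be positive")
  assert_that(censor_rate >= 0, "`censor_rate` must be >= 0")
  assert_that(admin_censor_months > 0, "`admin_censor_months` must be positive")
  for (coh in names(covariate_marginals)) {
    for (v in names(covariate_marginals[[coh]])) {
      p <- covariate_marginals[[coh]][[v]]
      assert_that(abs(sum(p) - 1) < 1e-6,
                  sprintf("frequencies of %s in cohort %s do not sum to 1",
                          v, coh))
      assert_that(all(p >= 0), "frequencies must be non-negative")
    }
  }
  structure(list(n_patients = n_patients, beta_risk = beta_risk,
                 beta_clinical = beta_clinical,
                 beta_treatment = beta_treatment,
                 beta_interaction = beta_interaction,
                 baseline_rate = baseline_rate, censor_rate = censor_rate,
                 admin_censor_months = admin_censor_months,
                 covariate_marginals = covariate_marginals,
                 seed = as.integer(seed)),
            class = "cohort_model")
}

#' Draw clinical covariates for one cohort
#'
#' I.i.d. draws from the per-cohort categorical marginals of the model.
#'
#' @param model A [cohort_model].
#' @param cohort Cohort label (`"primary"`, `"v1"`, `"v2"`, `"v3"`).
#' @param n Number of patients.
#' @param seed RNG seed.
#' @return Data frame of factor covariates with `cohort` attached.
#' @export
simulate_clinical <- function(model, cohort, n, seed) {
  assert_that(inherits(model, "cohort_model"), "`model` must be a cohort_model")
  assert_that(cohort %in% names(model$covariate_marginals),
              paste("unknown cohort label:", cohort))
  marg <- model$covariate_marginals[[cohort]]
  with_seed(seed, {
    cols <- lapply(marg, function(p)
      factor(sample(names(p), n, replace = TRUE, prob = p),
             levels = names(p)))
    out <- as.data.frame(cols, stringsAsFactors = FALSE)
    out$cohort <- cohort
    out
  })
}

#' Ordinal scores used in the ground-truth linear predictor
#' @noRd
clinical_scores <- function(covariates) {
  data.frame(
    pN = as.numeric(as.character(covariates$pN)),
    pT = match(as.character(covariates$pT), c("0", "1/2", "3/4")) - 1,
    clinical_stage = as.numeric(covariates$clinical_stage == "III"),
    cea = as.numeric(covariates$cea == ">=5"),
    location = match(as.character(covariates$location),
                     c(">10", "5-10", "<5")) - 1,
    neoadjuvant = as.numeric(as.character(covariates$neoadjuvant)))
}

#' Simulate proportional-hazards survival outcomes
#'
#' Event times are exponential with rate `baseline_rate * exp(lp)`; censoring
#' is the minimum of an independent exponential (rate `censor_rate`) and the
#' administrative cutoff. `event = 1` iff the event time is at most the
#' censoring time.
#'
#' @param linear_predictors Numeric vector of log relative hazards.
#' @param model A [cohort_model].
#' @param seed RNG seed.
#' @return Data frame with `time_months` and `event`.
#' @export
simulate_survival <- function(linear_predictors, model, seed) {
  assert_that(all(is.finite(linear_predictors)),
              "linear predictors must all be finite")
  assert_that(inherits(model, "cohort_model"), "`model` must be a cohort_model")
  n <- length(linear_predictors)
  with_seed(seed, {
    t_event <- stats::rexp(n, rate = model$baseline_rate *
                             exp(linear_predictors))
    t_cens <- if (model$censor_rate > 0)
      stats::rexp(n, rate = model$censor_rate) else rep(Inf, n)
    t_cens <- pmin(t_cens, model$admin_censor_months)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
    data.frame(time_months = pmax(time, 1e-6), event = event)
  })
}

#' Generate a full four-cohort synthetic study on disk
#'
#' For every patient: draws a latent risk `z ~ N(0,1)`, clinical covariates
#' from the cohort marginals, a DMFS outcome from the ground-truth linear
#' predictor, and (optionally) the phantom image pair plus tumor mask as
#' NIfTI files. Writes one directory per cohort containing the images, a
#' `survival.csv` table and a top-level `manifest.json` recording the ground
#' truth (latent risks, linear predictors, model and spec parameters) so
#' downstream recovery tests need no private state.
#'
#' @param model A [cohort_model].
#' @param spec A [phantom_spec].
#' @param dir Output directory (created if needed).
#' @param write_images Write NIfTI volumes (default TRUE). With FALSE only
#'   the tables and manifest are written; images can be regenerated
#'   deterministically from the per-patient seeds in the manifest.
#' @return Invisibly, a list with the combined `records` data frame (one row
#'   per patient, including `latent_risk` and per-patient `phantom_seed`) and
#'   the `manifest` path.
#' @export
generate_cohort <- function(model, spec, dir, write_images = TRUE) {
  assert_that(inherits(model, "cohort_model"), "`model` must be a cohort_model")
  assert_that(inherits(spec, "phantom_spec"), "`spec` must be a phantom_spec")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(dir), paste("cannot create output directory:", dir))

  records <- list()
  idx0 <- 0L
  for (coh in .cohort_names) {
    n <- model$n_patients[[coh]]
    cov <- simulate_clinical(model, coh, n, seed = model$seed + idx0 + 1L)
    z <- with_seed(model$seed + idx0 + 2L, stats::rnorm(n))
    sc <- clinical_scores(cov)
    tx <- as.numeric(as.character(cov$adjuvant_ct))
    bc <- model$beta_clinical
    lp_clin <- as.matrix(sc[, names(bc), drop = FALSE]) %*% bc
    lp <- model$beta_risk * z + as.vector(lp_clin) +
      model$beta_treatment * tx + model$beta_interaction * tx * (z > 0)
    surv <- simulate_survival(lp, model, seed = model$seed + idx0 + 3L)
    ids <- sprintf("%s_%03d", coh, seq_len(n))
    phantom_seeds <- (model$seed + 7919L * (idx0 + seq_len(n))) %% 2147483647L
    rec <- data.frame(patient_id = ids, surv, cov, latent_risk = z,
                      true_lp = as.vector(lp), phantom_seed = phantom_seeds,
                      stringsAsFactors = FALSE)
    cdir <- file.path(dir, coh)
    dir.create(cdir, showWarnings = FALSE)
    if (write_images) {
      for (i in seq_len(n)) {
        ph <- generate_phantom_pair(spec, z[i], seed = phantom_seeds[i])
        write_volume(ph$t2w, file.path(cdir, paste0(ids[i], "_t2w.nii.gz")))
        write_volume(ph$dwi_b0, file.path(cdir, paste0(ids[i], "_b0.nii.gz")))
        write_volume(ph$dwi_b1000,
                     file.path(cdir, paste0(ids[i], "_b1000.nii.gz")))
        write_volume(ph$mask, file.path(cdir, paste0(ids[i], "_mask.nii.gz")))
      }
    }
    utils::write.csv(rec[, setdiff(names(rec), c("true_lp"))],
                     file.path(cdir, "survival.csv"), row.names = FALSE)
    records[[coh]] <- rec
    idx0 <- idx0 + n + 10L
  }
  all_rec <- do.call(rbind, records)
  rownames(all_rec) <- NULL
  manifest <- list(
    generator = "radsig synthetic cohort",
    seed = model$seed,
    n_patients = as.list(model$n_patients),
    beta_risk = model$beta_risk,
    beta_clinical = as.list(model$beta_clinical),
    beta_treatment = model$beta_treatment,
    beta_interaction = model$beta_interaction,
    baseline_rate = model$baseline_rate,
    censor_rate = model$censor_rate,
    admin_censor_months = model$admin_censor_months,
    phantom = list(grid_shape = spec$grid_shape,
                   spacing_mm = spec$spacing_mm,
                   tumor_radius_range_mm = spec$tumor_radius_range_mm,
                   heterogeneity_link = spec$heterogeneity_link,
                   texture_correlation_length_mm =
                     spec$texture_correlation_length_mm),
    patients = all_rec[, c("patient_id", "cohort", "latent_risk", "true_lp",
                           "phantom_seed")])
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(records = all_rec, manifest = manifest_path, dir = dir))
}
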