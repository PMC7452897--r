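# End-to-end study orchestration: simulate -> extract -> select/fit ->
# stratify -> evaluate -> interaction -> report, with file-based stage
# caching so any intermediate can be deleted and reproduced.

#' Pipeline configuration
#'
#' Collects every tunable of the synthetic study and analysis chain. All
#' selection thresholds default to the study values: coarse filter top 20%
#' with p < 0.1, correlation cutoff |r| = 0.6, primary-median risk cutoff,
#' ICC retention 0.6, horizons 12/24/36 months.
#'
#' @param outdir Artifact directory.
#' @param model A [cohort_model] (ground-truth study design).
#' @param spec A [phantom_spec] (phantom geometry/texture).
#' @param n_bins Gray levels for texture/histogram features.
#' @param icc_screen Run the synthetic second-observer ICC screen.
#' @param icc_threshold ICC retention threshold.
#' @param perturb_magnitude Mask perturbation (voxels) for the second
#'   observer.
#' @param fraction,alpha,cor_cutoff,n_folds Selection parameters.
#' @param horizons Time-dependent ROC horizons (months).
#' @param eval_horizon Horizon for calibration, DCA, NRI and IDI (months).
#' @param write_images Write phantom NIfTI volumes to disk and read them
#'   back during extraction; with `FALSE` phantoms are regenerated in memory
#'   from the per-patient seeds recorded in the manifest.
#' @param use_cache Reuse stage outputs already present in `outdir`.
#' @param seed Seed for the LASSO fold assignment.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            model = cohort_model(),
                            spec = phantom_spec(),
                            n_bins = 32L,
                            icc_screen = TRUE,
                            icc_threshold = 0.6,
                            perturb_magnitude = 1L,
                            fraction = 0.20, alpha = 0.1,
                            cor_cutoff = 0.6, n_folds = 10,
                            horizons = c(12, 24, 36),
                            eval_horizon = 36,
                            write_images = FALSE,
                            use_cache = TRUE,
                            seed = 1L) {
  structure(list(outdir = outdir, model = model, spec = spec,
                 n_bins = as.integer(n_bins), icc_screen = icc_screen,
                 icc_threshold = icc_threshold,
                 perturb_magnitude = as.integer(perturb_magnitude),
                 fraction = fraction, alpha = alpha,
                 cor_cutoff = cor_cutoff, n_folds = n_folds,
                 horizons = horizons, eval_horizon = eval_horizon,
                 write_images = write_images, use_cache = use_cache,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Numeric clinical covariates used by the nomograms
#'
#' Ordinal scores of the clinicopathological factors: `pN` (0/1/2), `pT`
#' (0 = pT0, 1 = pT1-2, 2 = pT3-4), `clinical_stage` (III = 1), `cea`
#' (>= 5 = 1), `location` (>10 cm = 0, 5-10 = 1, <5 = 2).
#'
#' @param records Survival record table.
#' @return Data frame of numeric covariates.
#' @export
clinical_covariates <- function(records) {
  sc <- clinical_scores(records)
  sc[, c("pN", "pT", "clinical_stage", "cea", "location")]
}

#' Extract the 1240-feature vector of one phantom patient
#'
#' Derives the ADC map from the DWI pair, Z-normalises each sequence, and
#' extracts both 620-feature sequences.
#'
#' @param ph List from [generate_phantom_pair()] (or loaded volumes with the
#'   same names).
#' @param catalog Feature catalog.
#' @param mask Optional override mask (e.g. a perturbed second-observer
#'   mask); defaults to `ph$mask`.
#' @return Named numeric vector of length 1240.
#' @export
extract_phantom_patient <- function(ph, catalog = feature_catalog(),
                                    mask = NULL) {
  mask <- mask %||% ph$mask
  adc <- suppressWarnings(adc_from_dwi(ph$dwi_b0, ph$dwi_b1000))
  extract_patient(znormalize(ph$t2w), znormalize(adc), mask, mask, catalog)
}

#' Load (or regenerate) the phantom of one patient row
#' @noRd
patient_phantom <- function(row, config) {
  if (config$write_images) {
    cdir <- file.path(config$outdir, "cohorts", row$cohort)
    list(t2w = load_volume(file.path(cdir, paste0(row$patient_id,
                                                  "_t2w.nii.gz")), "T2W"),
         dwi_b0 = load_volume(file.path(cdir, paste0(row$patient_id,
                                                     "_b0.nii.gz")), "DWI_b0"),
         dwi_b1000 = load_volume(file.path(cdir,
                                           paste0(row$patient_id,
                                                  "_b1000.nii.gz")),
                                 "DWI_b1000"),
         mask = load_mask(file.path(cdir, paste0(row$patient_id,
                                                 "_mask.nii.gz"))))
  } else {
    generate_phantom_pair(config$spec, row$latent_risk,
                          seed = row$phantom_seed)
  }
}

#' Run the full pipeline
#'
#' Executes every stage, caching each stage's output under `outdir`
#' (`cohorts/`, `features.csv`, `features_rater_b.csv`, `icc.json`,
#' `signature.json`, `scores.csv`, `evaluation.json`, `interaction.csv`,
#' `report.txt`). Deleting any cached file and re-running reproduces it
#' deterministically.
#'
#' @param config A [pipeline_config].
#' @return List with `records`, `features`, `retained`, `signature`,
#'   `scores` (data frame with groups), `evaluation`, `interaction`, and
#'   file `paths`.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "pipeline_config"),
              "`config` must be a pipeline_config")
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cdir <- file.path(out, "cohorts")
  paths <- list(
    cohorts = cdir,
    features = file.path(out, "features.csv"),
    features_b = file.path(out, "features_rater_b.csv"),
    icc = file.path(out, "icc.json"),
    signature = file.path(out, "signature.json"),
    scores = file.path(out, "scores.csv"),
    evaluation = file.path(out, "evaluation.json"),
    interaction = file.path(out, "interaction.csv"),
    report = file.path(out, "report.txt"))

  ## stage 1: simulate -------------------------------------------------
  manifest_path <- file.path(cdir, "manifest.json")
  if (!(config$use_cache && file.exists(manifest_path))) {
    message("stage simulate: generating synthetic cohorts")
    generate_cohort(config$model, config$spec, cdir,
                    write_images = config$write_images)
  }
  records <- do.call(rbind, lapply(.cohort_names, function(coh) {
    utils::read.csv(file.path(cdir, coh, "survival.csv"),
                    stringsAsFactors = FALSE,
                    colClasses = c(pT = "character", pN = "character"))
  }))
  records$patient_id <- as.character(records$patient_id)

  ## stage 2: extract ---------------------------------------------------
  catalog <- feature_catalog(n_bins = config$n_bins)
  if (config$use_cache && file.exists(paths$features)) {
    features <- read_feature_table(paths$features)
  } else {
    message("stage extract: computing radiomic features")
    mat <- matrix(NA_real_, nrow(records), 1240L)
    for (i in seq_len(nrow(records))) {
      ph <- patient_phantom(records[i, ], config)
      v <- extract_phantom_patient(ph, catalog)
      if (i == 1L) colnames(mat) <- names(v)
      mat[i, ] <- v
    }
    features <- data.frame(patient_id = records$patient_id,
                           mat, check.names = FALSE,
                           stringsAsFactors = FALSE)
    write_feature_table(features, paths$features)
    features <- read_feature_table(paths$features)  # serialised values
  }

  ## stage 3: reproducibility screen ------------------------------------
  if (config$icc_screen) {
    if (config$use_cache && file.exists(paths$icc)) {
      retained <- jsonlite::read_json(paths$icc,
                                      simplifyVector = TRUE)$retained
    } else {
      message("stage icc: second-observer extraction on the primary cohort")
      prim <- records[records$cohort == "primary", , drop = FALSE]
      mat_b <- matrix(NA_real_, nrow(prim), 1240L)
      for (i in seq_len(nrow(prim))) {
        ph <- patient_phantom(prim[i, ], config)
        m2 <- perturb_mask(ph$mask, config$perturb_magnitude,
                           seed = prim$phantom_seed[i] + 1L)
        v <- extract_phantom_patient(ph, catalog, mask = m2)
        if (i == 1L) colnames(mat_b) <- names(v)
        mat_b[i, ] <- v
      }
      tab_b <- data.frame(patient_id = prim$patient_id, mat_b,
                          check.names = FALSE, stringsAsFactors = FALSE)
      write_feature_table(tab_b, paths$features_b)
      tab_a <- features[features$patient_id %in% prim$patient_id, ]
      icc <- suppressWarnings(
        compute_feature_icc(tab_a, tab_b, threshold = config$icc_threshold))
      retained <- icc$retained
      jsonlite::write_json(list(threshold = config$icc_threshold,
                                n_retained = length(retained),
                                retained = retained),
                           paths$icc, auto_unbox = TRUE, digits = NA)
    }
  } else retained <- setdiff(names(features), "patient_id")
  assert_that(length(retained) > 0, "ICC screen retained no features")

  ## stage 4: fit signature ----------------------------------------------
  prim_ids <- records$patient_id[records$cohort == "primary"]
  feat_use <- features[c("patient_id", retained)]
  if (config$use_cache && file.exists(paths$signature) &&
        file.exists(paths$scores)) {
    sig <- read_signature(paths$signature)
    scores_df <- utils::read.csv(paths$scores, stringsAsFactors = FALSE)
  } else {
    message("stage fit: coarse-to-fine selection + LASSO-Cox")
    sig <- radiomic_signature(
      feat_use[feat_use$patient_id %in% prim_ids, ],
      records[records$cohort == "primary",
              c("patient_id", "time_months", "event")],
      fraction = config$fraction, alpha = config$alpha,
      cor_cutoff = config$cor_cutoff, n_folds = config$n_folds,
      seed = config$seed)
    write_signature(sig, paths$signature)
    sc <- score(sig, feat_use)
    scores_df <- data.frame(patient_id = feat_use$patient_id,
                            score = unname(sc),
                            group = as.character(stratify(sig, sc)),
                            stringsAsFactors = FALSE)
    utils::write.csv(scores_df, paths$scores, row.names = FALSE)
    # downstream stages consume the serialised values so that cached and
    # fresh runs are bit-identical
    scores_df <- utils::read.csv(paths$scores, stringsAsFactors = FALSE)
    scores_df$patient_id <- as.character(scores_df$patient_id)
  }
  records <- merge(records, scores_df, by = "patient_id", sort = FALSE)
  records <- records[order(match(records$patient_id, features$patient_id)), ]

  ## stage 5: evaluate ----------------------------------------------------
  if (config$use_cache && file.exists(paths$evaluation)) {
    evaluation <- jsonlite::read_json(paths$evaluation, simplifyVector = TRUE)
  } else {
    message("stage evaluate: survival evaluation and nomograms")
    evaluation <- evaluate_study(records, config)
    jsonlite::write_json(evaluation, paths$evaluation, auto_unbox = TRUE,
                         digits = NA)
  }

  ## stage 6: interaction --------------------------------------------------
  if (config$use_cache && file.exists(paths$interaction)) {
    interaction <- utils::read.csv(paths$interaction,
                                   stringsAsFactors = FALSE)
  } else {
    message("stage interaction: subgroup chemotherapy efficacy")
    grp <- factor(records$group, levels = c("low", "high"))
    interaction <- rbind(
      subgroup_efficacy_table(records, grp, "all"),
      subgroup_efficacy_table(records, grp, "pT"),
      subgroup_efficacy_table(records, grp, "pN"))
    write_interaction_table(interaction, paths$interaction)
  }

  ## stage 7: report --------------------------------------------------------
  evaluation_loaded <- jsonlite::read_json(paths$evaluation,
                                           simplifyVector = TRUE)
  writeLines(render_report(evaluation_loaded, interaction), paths$report)

  list(records = records, features = features, retained = retained,
       signature = sig, scores = scores_df, evaluation = evaluation,
       interaction = interaction, paths = paths)
}

#' Survival evaluation across cohorts
#'
#' Computes, per cohort: high/low Kaplan-Meier separation (log-rank p and
#' group HR), time-dependent AUC at the configured horizons, and the
#' C-indexes of the signature, the clinical nomogram, and the radiomic
#' nomogram (both nomograms fitted on the primary cohort only); plus
#' calibration, decision curves, and NRI/IDI of the radiomic over the
#' clinical nomogram at `eval_horizon`.
#'
#' @param records Record table with `score` and `group` columns.
#' @param config A [pipeline_config].
#' @return Nested list of evaluation results.
#' @export
evaluate_study <- function(records, config) {
  prim <- records[records$cohort == "primary", , drop = FALSE]
  clin_prim <- clinical_covariates(prim)
  nom_clin <- build_nomogram(clin_prim, prim, horizons = config$horizons)
  nom_rad <- build_nomogram(cbind(clin_prim, signature = prim$score), prim,
                            horizons = config$horizons)
  h <- config$eval_horizon

  per_cohort <- lapply(.cohort_names, function(coh) {
    rec <- records[records$cohort == coh, , drop = FALSE]
    clin <- clinical_covariates(rec)
    hi <- rec[rec$group == "high", , drop = FALSE]
    lo <- rec[rec$group == "low", , drop = FALSE]
    lr <- logrank_test(hi, lo)
    hr <- tryCatch(
      fit_cox(data.frame(high = as.numeric(rec$group == "high")),
              rec)$table[1, c("hr", "hr_lower", "hr_upper")],
      error = function(e) data.frame(hr = NA, hr_lower = NA, hr_upper = NA))
    auc <- time_dependent_auc(rec$score, rec, horizons = config$horizons)
    ci_sig <- harrell_cindex(rec$score, rec)
    lp_clin <- stats::predict(nom_clin$cox$fit, newdata = clin,
                              type = "lp", reference = "zero")
    lp_rad <- stats::predict(nom_rad$cox$fit,
                             newdata = cbind(clin, signature = rec$score),
                             type = "lp", reference = "zero")
    ci_clin <- harrell_cindex(unname(lp_clin), rec)
    ci_rad <- harrell_cindex(unname(lp_rad), rec)
    risk_clin <- 1 - predict_dmfs(nom_clin, clin, horizon = h)
    risk_rad <- 1 - predict_dmfs(nom_rad,
                                 cbind(clin, signature = rec$score),
                                 horizon = h)
    calib <- calibration_curve(1 - risk_rad, rec, horizon = h)
    dca <- decision_curve(risk_rad, rec, horizon = h)
    nri <- compute_nri(risk_clin, risk_rad, rec, horizon = h)
    idi <- compute_idi(risk_clin, risk_rad, rec, horizon = h)
    list(cohort = coh, n = nrow(rec),
         n_high = nrow(hi), n_low = nrow(lo),
         logrank_p = lr$p, hr_high_vs_low = hr$hr,
         hr_lower = hr$hr_lower, hr_upper = hr$hr_upper,
         auc = as.list(auc),
         cindex_signature = ci_sig$c,
         cindex_signature_ci = c(ci_sig$lower, ci_sig$upper),
         cindex_clinical_nomogram = ci_clin$c,
         cindex_clinical_ci = c(ci_clin$lower, ci_clin$upper),
         cindex_radiomic_nomogram = ci_rad$c,
         cindex_radiomic_ci = c(ci_rad$lower, ci_rad$upper),
         calibration = calib, decision_curve = dca,
         nri = nri$nri, idi = idi$idi)
  })
  names(per_cohort) <- .cohort_names
  list(eval_horizon = h, cohorts = per_cohort)
}

#' Render the human-readable study report
#' @noRd
render_report <- function(evaluation, interaction) {
  lines <- c("Radiomic signature study report",
             "===============================", "")
  lines <- c(lines, "Cohort overview and risk stratification", "")
  for (coh in names(evaluation$cohorts)) {
    e <- evaluation$cohorts[[coh]]
    auc <- unlist(e$auc)
    lines <- c(lines, sprintf(
      "  %-8s n=%3d (high %3d / low %3d)  log-rank p=%.3g  HR=%.3g (%.3g-%.3g)",
      coh, e$n, e$n_high, e$n_low, e$logrank_p, e$hr_high_vs_low,
      e$hr_lower, e$hr_upper),
      sprintf("           AUC(12/24/36 mo) = %.3f / %.3f / %.3f",
              auc[1], auc[2], auc[3]))
  }
  lines <- c(lines, "", "C-index grid",
             sprintf("  %-8s %-10s %-18s %-18s", "cohort", "signature",
                     "clinical nomogram", "radiomic nomogram"))
  for (coh in names(evaluation$cohorts)) {
    e <- evaluation$cohorts[[coh]]
    lines <- c(lines, sprintf("  %-8s %-10.3f %-18.3f %-18.3f", coh,
                              e$cindex_signature, e$cindex_clinical_nomogram,
                              e$cindex_radiomic_nomogram))
  }
  lines <- c(lines, "",
             sprintf("Incremental value at %g months (radiomic vs clinical nomogram)",
                     evaluation$eval_horizon))
  for (coh in names(evaluation$cohorts)) {
    e <- evaluation$cohorts[[coh]]
    lines <- c(lines, sprintf("  %-8s NRI=%+.3f  IDI=%+.3f", coh, e$nri,
                              e$idi))
  }
  lines <- c(lines, "", "Chemotherapy-by-signature subgroups", "")
  for (i in seq_len(nrow(interaction))) {
    r <- interaction[i, ]
    hrtxt <- if (is.finite(r$hr))
      sprintf("%.2f (%.2f-%.2f)", r$hr, r$hr_lower, r$hr_upper) else "NA"
    lines <- c(lines, sprintf(
      "  %-8s %-5s CT %3d / no CT %3d  HR(CT)=%-18s p=%-8.3g p_int=%.3g",
      r$subgroup, r$signature_group, r$n_ct, r$n_no_ct, hrtxt,
      r$p_logrank, r$p_interaction))
  }
  lines
}
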