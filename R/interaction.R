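# Treatment-by-biomarker interaction analysis: subgroup chemotherapy-efficacy
# hazard ratios and Cox product-term interaction tests.

#' Treatment-by-factor interaction test
#'
#' Fits a Cox model with both main effects and their product and returns the
#' Wald p-value of the product coefficient. Both factors must be binary
#' (0/1, logical, or two-level factors); dichotomise first otherwise.
#'
#' @param records Survival records containing the two factor columns.
#' @param factor_a,factor_b Column names of the two factors.
#' @return List with `p_interaction`, `coef_interaction`, and the `cox_fit`.
#' @export
interaction_test <- function(records, factor_a, factor_b) {
  check_records(records)
  as_bin <- function(v, nm) {
    if (is.factor(v)) {
      assert_that(nlevels(droplevels(v)) == 2L,
                  sprintf("factor %s must have exactly 2 observed levels", nm))
      as.numeric(v == levels(droplevels(v))[2])
    } else {
      u <- unique(v)
      assert_that(length(u) == 2L,
                  sprintf("factor %s must take exactly 2 values", nm))
      as.numeric(v == max(u))
    }
  }
  a <- as_bin(records[[factor_a]], factor_a)
  b <- as_bin(records[[factor_b]], factor_b)
  tab <- table(a, b)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: %s=%s & %s=%s", factor_a,
                 rownames(tab)[empty[1]], factor_b, colnames(tab)[empty[2]]))
  }
  cov <- data.frame(a = a, b = b, ab = a * b)
  names(cov) <- c(factor_a, factor_b,
                  paste0(factor_a, ":", factor_b))
  cf <- fit_cox(cov, records)
  row <- cf$table[3, ]
  list(p_interaction = row$p, coef_interaction = row$coef, cox_fit = cf)
}

#' Subgroup chemotherapy-efficacy table
#'
#' For each level of a pathological stage variable crossed with the high/low
#' signature group, reports treated/untreated counts, the within-cell Cox
#' hazard ratio of chemotherapy (CT vs no CT) with 95% CI, the two-sided
#' log-rank p, and the stratum's signature-by-chemotherapy interaction p
#' (Cox product term within the stage level). Cells in which the HR is
#' inestimable (events missing in an arm, non-convergence) report `NA` with a
#' reason; subgroups with fewer than 2 subjects per arm are flagged, not
#' dropped.
#'
#' @param records Survival records with an `adjuvant_ct` column (0/1 or
#'   two-level factor).
#' @param signature_groups Factor of `low`/`high` signature groups, aligned
#'   with `records`.
#' @param stage_variable `"pT"`, `"pN"`, or `"all"` (no stage split).
#' @return Data frame with one row per stage level x signature group.
#' @export
subgroup_efficacy_table <- function(records, signature_groups,
                                    stage_variable = c("all", "pT", "pN")) {
  stage_variable <- match.arg(stage_variable)
  check_records(records)
  assert_that(length(signature_groups) == nrow(records),
              "`signature_groups` must match `records`")
  tx <- records$adjuvant_ct
  tx <- if (is.factor(tx)) as.numeric(as.character(tx)) else as.numeric(tx)
  assert_that(all(tx %in% c(0, 1)), "`adjuvant_ct` must be 0/1")
  rs_high <- signature_groups == "high"

  strata <- if (stage_variable == "all") list(all = rep(TRUE, nrow(records)))
            else {
              v <- records[[stage_variable]]
              lv <- if (is.factor(v)) levels(v) else sort(unique(v))
              stats::setNames(lapply(lv, function(l) v == l),
                              paste0(stage_variable, "=", lv))
            }

  rows <- list()
  for (sname in names(strata)) {
    sel <- strata[[sname]]
    p_int <- tryCatch({
      dat <- records[sel, , drop = FALSE]
      dat$rs <- as.numeric(rs_high[sel])
      dat$ct <- tx[sel]
      interaction_test(dat, "rs", "ct")$p_interaction
    }, error = function(e) NA_real_)
    for (grp in c("high", "low")) {
      cell <- sel & (rs_high == (grp == "high"))
      n_ct <- sum(cell & tx == 1)
      n_noct <- sum(cell & tx == 0)
      hr <- lo <- hi <- NA_real_
      p_lr <- NA_real_
      note <- ""
      if (n_ct >= 1 && n_noct >= 1) {
        rec_cell <- records[cell, , drop = FALSE]
        tx_cell <- tx[cell]
        p_lr <- tryCatch(
          logrank_test(rec_cell[tx_cell == 1, ], rec_cell[tx_cell == 0, ])$p,
          warning = function(w) 1, error = function(e) NA_real_)
        fitres <- tryCatch({
          cf <- fit_cox(data.frame(ct = tx_cell), rec_cell)
          cf$table[1, c("hr", "hr_lower", "hr_upper")]
        }, error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(fitres)) {
          hr <- fitres$hr; lo <- fitres$hr_lower; hi <- fitres$hr_upper
          if (!is.finite(hr) || hr > 1e6 || hr < 1e-6) {
            hr <- lo <- hi <- NA_real_
            note <- "HR inestimable (no events in an arm)"
          }
        } else note <- "HR inestimable (no events in an arm)"
      } else note <- "empty treatment arm"
      if (min(n_ct, n_noct) < 2) note <- paste(note, "(<2 per arm)")
      rows[[length(rows) + 1L]] <- data.frame(
        subgroup = sname, signature_group = grp,
        n_ct = n_ct, n_no_ct = n_noct,
        hr = hr, hr_lower = lo, hr_upper = hi,
        p_logrank = p_lr, p_interaction = p_int,
        note = trimws(note), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a subgroup efficacy table as delimited text
#'
#' @param table Output of [subgroup_efficacy_table()].
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
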