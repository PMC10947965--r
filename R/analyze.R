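#' Full cohort analysis: selection, robust regression, FDR, interactions
#'
#' Runs the cohort-level chain on one pathology-specific feature panel:
#' log-transform the UWMC features (zeros to 0.05), stability-select the
#' stable predictors of the outcome, fit each selected predictor's Huber
#' regression in the full sample and in each racialized-group stratum,
#' apply Benjamini-Hochberg control separately within each analysis column
#' (full sample, BA, nHW - each column is one testing family), and fit the
#' group-by-predictor interaction only where exactly one stratum's test was
#' rejected.
#'
#' @param data Cohort data frame with `moca`, the covariates of
#'   [moca_covariates()], and raw (untransformed) feature columns in
#'   \[0, 1\].
#' @param features Candidate feature column names.
#' @param q FDR level (default 0.05).
#' @param zero_substitute Zero substitution used before the log transform.
#' @param ... Passed to [stability_select()] (`n_reps`,
#'   `holdout_fraction`, `frequency_threshold`, `alpha`, `cv_folds`,
#'   `seed`).
#' @return An object of class `uwmc_analysis`: `selection`
#'   (`uwmc_selection`), `results` (one row per selected predictor with
#'   full/BA/nHW betas, p-values, FDR flags, per-percent effects, and the
#'   interaction p where tested), and the three `uwmc_fdr` decisions.
#' @export
analyze_uwmc_cohort <- function(data, features, q = 0.05,
                                zero_substitute = 0.05, ...) {
  df <- as.data.frame(data)
  for (f in features) df[[f]] <- log_transform(df[[f]], zero_substitute)
  selection <- stability_select(df, features, ...)
  sel <- selection$selected
  if (!length(sel)) {
    return(structure(list(selection = selection,
                          results = tibble(), fdr = list()),
                     class = "uwmc_analysis"))
  }
  fit_col <- function(stratum) {
    lapply(sel, function(f) huber_regression(df, f, stratum = stratum)$result)
  }
  full <- dplyr::bind_rows(fit_col("full"))
  ba <- dplyr::bind_rows(fit_col("BA"))
  nhw <- dplyr::bind_rows(fit_col("nHW"))
  fdr_full <- bh_fdr(stats::setNames(full$p, sel), q)
  fdr_ba <- bh_fdr(stats::setNames(ba$p, sel), q)
  fdr_nhw <- bh_fdr(stats::setNames(nhw$p, sel), q)
  inter_p <- vapply(sel, function(f) {
    fit <- conditional_interaction(df, f, fdr_ba, fdr_nhw)
    if (is.null(fit)) NA_real_ else fit$result$p
  }, numeric(1))
  results <- tibble(
    predictor = sel,
    beta_full = full$beta, p_full = full$p,
    fdr_full = sel %in% fdr_full$rejected,
    per_percent_full = per_percent_effect(full$beta),
    beta_ba = ba$beta, p_ba = ba$p, fdr_ba = sel %in% fdr_ba$rejected,
    beta_nhw = nhw$beta, p_nhw = nhw$p, fdr_nhw = sel %in% fdr_nhw$rejected,
    interaction_p = unname(inter_p))
  structure(list(selection = selection, results = results,
                 fdr = list(full = fdr_full, BA = fdr_ba, nHW = fdr_nhw)),
            class = "uwmc_analysis")
}

#' @export
print.uwmc_analysis <- function(x, ...) {
  print(x$selection)
  if (nrow(x$results)) print(x$results) else cat("no features selected\n")
  invisible(x)
}

#' @export
tidy.uwmc_analysis <- function(x, ...) x$results

#' @export
glance.uwmc_analysis <- function(x, ...) {
  tibble(n_candidates = nrow(x$selection$frequency),
         n_selected = length(x$selection$selected),
         n_fdr_full = if (length(x$fdr)) x$fdr$full$n_rejected else 0L)
}

#' Format a p-value the way cohort reports print it
#'
#' Values below the floor print as `"< 0.0001"`; otherwise up to 4
#' significant decimals.
#'
#' @param p Numeric p-values.
#' @param floor Reporting floor.
#' @return Character vector.
#' @export
format_p <- function(p, floor = 1e-4) {
  ifelse(is.na(p), "-",
         ifelse(p < floor, paste("<", format(floor, scientific = FALSE)),
                formatC(signif(p, 2), format = "fg")))
}
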