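#' Default adjustment covariates for cognition models
#'
#' The forced covariate set used throughout the pipeline: age, sex,
#' racialized group, education, weekly physical activity, diabetes,
#' hypertension, high cholesterol, and APOE e4 carrier status. These enter
#' every elastic-net run unpenalized and every robust regression as
#' adjustment terms (racialized group only in full-sample models).
#'
#' @return Character vector of column names.
#' @export
moca_covariates <- function() {
  c("age", "sex", "group", "education", "physical_activity",
    "diabetes", "hypertension", "high_cholesterol", "apoe4")
}

#' Log transform with zero substitution
#'
#' Natural logarithm after replacing exact zeros with a small positive
#' substitute (default 0.05). Connectivity fractions and lesion volumes are
#' right-skewed with genuine zeros (pairs no streamline of which crosses a
#' lesion), and the zeros are retained as data rather than dropped; the
#' substitution keeps them in the model. Natural log is what makes the
#' "coefficient / 100 per 1% greater predictor" reporting rule valid, since
#' beta * ln(1.01) ~ beta / 100.
#'
#' @param x Non-negative numeric vector.
#' @param zero_substitute Value substituted for exact zeros before taking
#'   the log.
#' @return `log(x)` with zeros mapped to `log(zero_substitute)`.
#' @examples
#' log_transform(c(1, 0, exp(1)))
#' @export
log_transform <- function(x, zero_substitute = 0.05) {
  if (any(x < 0, na.rm = TRUE)) abort("`x` must be non-negative")
  log(ifelse(x > 0, x, zero_substitute))
}

#' Per-percent effect from a log-scale coefficient
#'
#' A coefficient on a natural-log predictor, divided by 100, is the outcome
#' difference associated with a 1% greater predictor (first-order in
#' ln(1.01) ~ 0.01). Summaries report it rounded to 3 decimals.
#'
#' @param beta Numeric coefficient(s) from a model with an ln-transformed
#'   predictor.
#' @return `beta / 100`, exactly.
#' @examples
#' per_percent_effect(-3.03)  # -0.0303: a 0.030-point lower score per 1%
#' @export
per_percent_effect <- function(beta) beta / 100

build_covariate_frame <- function(data, covariates) {
  cov <- as.data.frame(data[covariates])
  if ("group" %in% names(cov)) cov$group <- as.numeric(cov$group == "BA")
  for (nm in names(cov)) {
    if (is.logical(cov[[nm]])) cov[[nm]] <- as.numeric(cov[[nm]])
    if (is.character(cov[[nm]]) || is.factor(cov[[nm]]))
      abort(sprintf("covariate '%s' is not numeric or binary-codable", nm))
  }
  cov
}

#' Resampled elastic-net stability selection of UWMC features
#'
#' Screens a large panel of candidate connectivity features down to the
#' stable predictors of the outcome. Each repetition holds out a fresh
#' simple random `holdout_fraction` of participants, standardizes the
#' candidate features on the remaining training rows, and fits an elastic
#' net of the outcome on candidates plus the forced covariates (covariates
#' unpenalized via a zero penalty factor; outcome unstandardized), with the
#' penalty chosen by `cv_folds`-fold cross-validated mean squared error. A
#' feature is "chosen" in a repetition iff its coefficient at the selected
#' penalty is nonzero; features chosen in at least
#' `frequency_threshold` of the `n_reps` repetitions form the selected set.
#'
#' All randomness (subsampling and fold assignment) derives from
#' `seed + repetition index`, so a fixed seed reproduces the frequency map
#' bit-exactly and results do not depend on feature column order.
#'
#' @param data A data frame with the outcome, covariates, and candidate
#'   feature columns. Candidate features should already be on the
#'   log scale (see [log_transform()]).
#' @param features Character vector of candidate feature column names.
#' @param outcome Outcome column name (default `"moca"`).
#' @param covariates Forced covariate column names; see [moca_covariates()].
#' @param n_reps Number of resampling repetitions (default 120).
#' @param holdout_fraction Fraction removed each repetition (default 0.10).
#' @param frequency_threshold Selection frequency cutoff (default 0.90).
#' @param alpha Elastic-net mixing parameter in (0, 1] (default 0.5).
#' @param cv_folds Cross-validation folds for the penalty (default 10).
#' @param penalty_choice `"1se"` (default): the largest penalty within one
#'   standard error of the cross-validated MSE minimum, the standard
#'   parsimonious choice for screening; `"min"`: the MSE-minimizing
#'   penalty, which admits many spurious features into every refit and
#'   defeats the frequency filter.
#' @param seed Master seed.
#' @return An object of class `uwmc_selection` with a `frequency` tibble
#'   (`feature`, `frequency`, `selected`), the `selected` character vector,
#'   and the configuration. `tidy()` returns the frequency tibble;
#'   `autoplot()` draws it.
#' @export
stability_select <- function(data, features, outcome = "moca",
                             covariates = moca_covariates(),
                             n_reps = 120L, holdout_fraction = 0.10,
                             frequency_threshold = 0.90, alpha = 0.5,
                             cv_folds = 10L, penalty_choice = c("1se", "min"),
                             seed = 1L) {
  penalty_choice <- match.arg(penalty_choice)
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    abort("`holdout_fraction` must be in (0, 1)")
  if (frequency_threshold <= 0 || frequency_threshold > 1)
    abort("`frequency_threshold` must be in (0, 1]")
  y <- data[[outcome]]
  n <- length(y)
  if (n <= cv_folds) abort("need more participants than cross-validation folds")
  x_cand <- as.matrix(data[features])
  const <- apply(x_cand, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warn(paste0("dropping constant features: ",
                paste(features[const], collapse = ", ")))
    features <- features[!const]
    x_cand <- x_cand[, !const, drop = FALSE]
  }
  if (!ncol(x_cand)) abort("no non-constant candidate features remain")
  x_cov <- as.matrix(build_covariate_frame(data, covariates))
  if (qr(cbind(1, x_cov))$rank < ncol(x_cov) + 1L)
    abort("covariate matrix is singular")
  p_cand <- ncol(x_cand)
  n_train <- round((1 - holdout_fraction) * n)
  pf <- c(rep(1, p_cand), rep(0, ncol(x_cov)))
  chosen <- matrix(FALSE, n_reps, p_cand)
  for (r in seq_len(n_reps)) {
    draws <- withr::with_seed(seed + r, list(
      idx = sample.int(n, n_train),
      foldid = sample(rep_len(seq_len(cv_folds), n_train))
    ))
    xc <- x_cand[draws$idx, , drop = FALSE]
    mu <- colMeans(xc)
    sdev <- apply(xc, 2, stats::sd)
    ok <- sdev > 0
    xc <- sweep(xc, 2, mu, "-")
    xc[, ok] <- sweep(xc[, ok, drop = FALSE], 2, sdev[ok], "/")
    xc[, !ok] <- 0
    cv <- glmnet::cv.glmnet(cbind(xc, x_cov[draws$idx, , drop = FALSE]),
                            y[draws$idx], alpha = alpha, foldid = draws$foldid,
                            penalty.factor = pf, standardize = FALSE,
                            nlambda = 60)
    beta <- as.numeric(stats::coef(cv, s = paste0("lambda.", penalty_choice)))[1 + seq_len(p_cand)]
    chosen[r, ] <- beta != 0 & ok
  }
  freq <- colMeans(chosen)
  frequency <- tibble(feature = features, frequency = freq,
                      selected = freq >= frequency_threshold)
  structure(list(
    frequency = frequency,
    selected = features[frequency$selected],
    n_reps = n_reps, holdout_fraction = holdout_fraction,
    frequency_threshold = frequency_threshold, alpha = alpha,
    cv_folds = cv_folds, penalty_choice = penalty_choice, seed = seed
  ), class = "uwmc_selection")
}

#' @export
print.uwmc_selection <- function(x, ...) {
  cat(sprintf("<uwmc_selection> %d/%d features selected (threshold %.2f, %d reps)\n",
              length(x$selected), nrow(x$frequency), x$frequency_threshold, x$n_reps))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.uwmc_selection <- function(x, ...) dplyr::arrange(x$frequency, dplyr::desc(.data$frequency))

#' @importFrom generics glance
#' @export
glance.uwmc_selection <- function(x, ...) {
  tibble(n_features = nrow(x$frequency), n_selected = length(x$selected),
         n_reps = x$n_reps, frequency_threshold = x$frequency_threshold,
         alpha = x$alpha, cv_folds = x$cv_folds, seed = x$seed)
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.uwmc_selection <- function(object, ...) {
  df <- tidy(object)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$feature,
                                   colour = .data$selected)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$frequency_threshold, linetype = 2) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "selection frequency", y = NULL, colour = "selected") +
    ggplot2::theme_minimal()
}

#' Robust (Huber M) regression of cognition on one connectivity predictor
#'
#' Fits an M-estimated linear model by iteratively reweighted least squares
#' with the Huber psi (tuning constant 1.345 for 95% Gaussian efficiency;
#' scale re-estimated by MAD each iteration), limiting the influence of the
#' outlying connectivity values these data exhibit. The model is
#' `outcome ~ ln(predictor) + covariates`; racialized group is included
#' only in full-sample models. With `with_interaction = TRUE` a
#' group-by-predictor interaction term is added and reported as the focal
#' term. P-values use the large-sample normal approximation on the robust
#' standard error.
#'
#' @param data Cohort data frame; the predictor column must already be on
#'   the log scale.
#' @param predictor Name of the (log-scale) predictor column.
#' @param outcome Outcome column (default `"moca"`).
#' @param covariates Adjustment covariates; see [moca_covariates()].
#' @param stratum `"full"`, `"BA"`, or `"nHW"`; strata filter on the
#'   `group` column and drop `group` from the covariates.
#' @param with_interaction Add and report `group x predictor`
#'   (full sample only).
#' @param k Huber tuning constant.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on
#'   coefficient change.
#' @return An object of class `uwmc_huber`: the `MASS::rlm` fit plus a
#'   one-row `result` tibble (`predictor`, `stratum`, `n`, `beta`, `se`,
#'   `statistic`, `p`, `per_percent_effect`). `tidy()` gives the full
#'   coefficient table; `glance()` gives fit-level summaries.
#' @export
huber_regression <- function(data, predictor, outcome = "moca",
                             covariates = moca_covariates(),
                             stratum = c("full", "BA", "nHW"),
                             with_interaction = FALSE,
                             k = 1.345, max_iter = 100L, tol = 1e-8) {
  stratum <- match.arg(stratum)
  if (with_interaction && stratum != "full")
    abort("interaction models are fitted in the full sample only")
  df <- as.data.frame(data)
  if (stratum != "full") {
    df <- df[df$group == stratum, , drop = FALSE]
    covariates <- setdiff(covariates, "group")
  }
  cov <- build_covariate_frame(df, covariates)
  mf <- cbind(data.frame(.y = df[[outcome]], .x = df[[predictor]]), cov)
  rhs <- c(".x", colnames(cov))
  if (with_interaction) {
    mf$.xg <- mf$.x * mf$group
    rhs <- c(rhs, ".xg")
  }
  if (nrow(mf) < ncol(mf) + 2L)
    abort(sprintf("stratum '%s' has too few rows (%d) for %d model terms",
                  stratum, nrow(mf), length(rhs)))
  fml <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  fit <- MASS::rlm(fml, data = mf, psi = MASS::psi.huber, k = k,
                   scale.est = "MAD", maxit = max_iter, acc = tol)
  focal <- if (with_interaction) ".xg" else ".x"
  co <- summary(fit)$coefficients
  beta <- co[focal, "Value"]
  se <- co[focal, "Std. Error"]
  z <- beta / se
  res <- tibble(predictor = predictor,
                stratum = if (with_interaction) "interaction" else stratum,
                n = nrow(mf), beta = beta, se = se, statistic = z,
                p = 2 * stats::pnorm(-abs(z)),
                per_percent_effect = per_percent_effect(beta))
  structure(list(fit = fit, focal = focal, predictor = predictor,
                 stratum = stratum, with_interaction = with_interaction,
                 result = res),
            class = "uwmc_huber")
}

#' @export
print.uwmc_huber <- function(x, ...) {
  r <- x$result
  cat(sprintf("<uwmc_huber> %s [%s]: beta %.3f (SE %.3f, p %.2g); %.3f points per 1%%\n",
              r$predictor, r$stratum, r$beta, r$se, r$p, r$per_percent_effect))
  invisible(x)
}

#' @export
tidy.uwmc_huber <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  term <- rownames(co)
  term[term == ".x"] <- x$predictor
  term[term == ".xg"] <- paste0(x$predictor, ":group")
  tibble(term = term, estimate = co[, "Value"], std.error = co[, "Std. Error"],
         statistic = co[, "Value"] / co[, "Std. Error"],
         p.value = 2 * stats::pnorm(-abs(co[, "Value"] / co[, "Std. Error"])))
}

#' @export
glance.uwmc_huber <- function(x, ...) {
  tibble(n = x$result$n, sigma = x$fit$s, converged = x$fit$converged,
         stratum = x$result$stratum)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard step-up procedure: order the m p-values ascending, find the
#' largest k with `p_(k) <= k q / m`, and reject the k smallest. Adjusted
#' p-values use the usual monotone formula, so the rejection set equals
#' `{adjusted p <= q}`. One call corresponds to one analysis family (for
#' example, the full-sample column of one pathology-set analysis).
#'
#' @param pvalues Named numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return An object of class `uwmc_fdr`: `q`, `adjusted_p` (named),
#'   `rejected` (names), `n_rejected`. `tidy()` returns a tibble.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (length(pvalues) && (any(pvalues < 0, na.rm = TRUE) || any(pvalues > 1, na.rm = TRUE)))
    abort("p-values must lie in [0, 1]")
  if (is.null(names(pvalues))) names(pvalues) <- as.character(seq_along(pvalues))
  keep <- !is.na(pvalues)
  adj <- rep(NA_real_, length(pvalues))
  names(adj) <- names(pvalues)
  adj[keep] <- stats::p.adjust(pvalues[keep], method = "BH")
  rejected <- names(pvalues)[keep & adj <= q]
  structure(list(q = q, pvalues = pvalues, adjusted_p = adj,
                 rejected = rejected, n_rejected = length(rejected)),
            class = "uwmc_fdr")
}

#' @export
print.uwmc_fdr <- function(x, ...) {
  cat(sprintf("<uwmc_fdr> %d/%d rejected at q = %g\n",
              x$n_rejected, sum(!is.na(x$pvalues)), x$q))
  invisible(x)
}

#' @export
tidy.uwmc_fdr <- function(x, ...) {
  tibble(id = names(x$pvalues), p = unname(x$pvalues),
         adjusted_p = unname(x$adjusted_p),
         rejected = names(x$pvalues) %in% x$rejected)
}

#' Conditional interaction test after stratified FDR decisions
#'
#' The group-by-predictor interaction is tested in the full sample only
#' when the stratified analyses disagree: the predictor's test was rejected
#' in exactly one of the two racialized-group strata. When both strata
#' rejected, or neither did, no interaction model is fitted and `NULL` is
#' returned (rendered "-" in reports).
#'
#' @param data Full-sample cohort data frame.
#' @param predictor Predictor column name, which must appear as an id in
#'   both FDR decisions.
#' @param fdr_ba,fdr_nhw `uwmc_fdr` decisions for the BA and nHW strata.
#' @param ... Passed to [huber_regression()].
#' @return A `uwmc_huber` interaction fit, or `NULL`.
#' @export
conditional_interaction <- function(data, predictor, fdr_ba, fdr_nhw, ...) {
  in_ba <- predictor %in% fdr_ba$rejected
  in_nhw <- predictor %in% fdr_nhw$rejected
  if (xor(in_ba, in_nhw))
    huber_regression(data, predictor, stratum = "full", with_interaction = TRUE, ...)
  else
    NULL
}

#' Spearman agreement between lobar UWMC and lobar WMH volume
#'
#' Rank correlation (average ranks for ties) with a two-sided p-value,
#' used as the proof-of-concept check that the connectivity-based lesion
#' measure tracks conventional lobar lesion volume.
#'
#' @param lobar_uwmc,lobar_wmh Paired numeric vectors (n >= 3).
#' @return A one-row tibble with `rho`, `p.value`, `n`.
#' @export
spearman_validation <- function(lobar_uwmc, lobar_wmh) {
  if (length(lobar_uwmc) != length(lobar_wmh) || length(lobar_uwmc) < 3)
    abort("need paired vectors of length >= 3")
  if (stats::sd(lobar_uwmc) == 0 || stats::sd(lobar_wmh) == 0)
    abort("constant vector: rank correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(lobar_uwmc, lobar_wmh, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p.value = ct$p.value, n = length(lobar_uwmc))
}

#' Descriptive comparison of participant characteristics between two groups
#'
#' Continuous variables are summarised as median (Q1, Q3) and compared by
#' Mann-Whitney U; categorical variables as n (%) and compared by Pearson
#' chi-square, switching to Fisher's exact test when any expected cell
#' count is below 5. The median split assigns values exactly at the median
#' to the high group.
#'
#' @param data Cohort data frame.
#' @param split `"group"` (racialized group column) or
#'   `"global_uwmc_median"` (median split of the `global_uwmc` column).
#' @param variables Columns to describe; defaults to every column except
#'   the one defining the split.
#' @return A tibble with one row per variable: `variable`, `type`, the two
#'   group labels and summaries, `test`, `p.value`.
#' @export
describe_groups <- function(data, split = c("group", "global_uwmc_median"),
                            variables = NULL) {
  split <- match.arg(split)
  df <- as.data.frame(data)
  if (split == "group") {
    g <- factor(df$group)
    drop_var <- "group"
  } else {
    if (is.null(df$global_uwmc)) abort("median split needs a `global_uwmc` column")
    med <- stats::median(df$global_uwmc)
    g <- factor(ifelse(df$global_uwmc >= med, "high", "low"), levels = c("low", "high"))
    drop_var <- "global_uwmc"
  }
  if (nlevels(g) != 2 || any(table(g) == 0))
    abort("both comparison groups must be non-empty")
  variables <- variables %||% setdiff(names(df), drop_var)
  rows <- lapply(variables, function(v) {
    x <- df[[v]]
    categorical <- is.logical(x) || is.character(x) || is.factor(x) ||
      length(unique(x)) <= 2
    if (!categorical) {
      s <- vapply(levels(g), function(l) {
        q <- stats::quantile(x[g == l], c(0.5, 0.25, 0.75))
        sprintf("%.3g (%.3g, %.3g)", q[1], q[2], q[3])
      }, "")
      p <- suppressWarnings(stats::wilcox.test(x ~ g, exact = FALSE)$p.value)
      test <- "mann-whitney"
    } else {
      tab <- table(factor(x), g)
      expected <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$expected
      if (any(expected < 5)) {
        p <- stats::fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
        test <- "chi-square"
      }
      top <- rownames(tab)[nrow(tab)]      # highest level, e.g. TRUE/1
      s <- vapply(levels(g), function(l) {
        n1 <- tab[top, l]; ntot <- sum(tab[, l])
        sprintf("%d (%.1f%%)", n1, 100 * n1 / ntot)
      }, "")
    }
    tibble(variable = v, type = if (categorical) "categorical" else "continuous",
           group1 = levels(g)[1], summary1 = s[1],
           group2 = levels(g)[2], summary2 = s[2],
           test = test, p.value = p)
  })
  dplyr::bind_rows(rows)
}
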