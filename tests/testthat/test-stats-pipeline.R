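test_that("the log transform substitutes zeros and rejects negatives", {
  expect_equal(log_transform(1), 0)
  expect_equal(log_transform(0), log(0.05))
  expect_equal(log_transform(exp(1)), 1)
  expect_equal(log_transform(0, zero_substitute = 0.1), log(0.1))
  expect_error(log_transform(-1), "non-negative")
})

test_that("per-percent effects are beta/100, linear, and sign-preserving", {
  expect_equal(round(per_percent_effect(-3.03), 3), -0.030)
  expect_equal(round(per_percent_effect(-2.26), 3), -0.023)
  expect_equal(per_percent_effect(0), 0)
  b <- c(-5, -0.1, 0.2, 7)
  expect_equal(per_percent_effect(2 * b), 2 * per_percent_effect(b))
  expect_equal(sign(per_percent_effect(b)), sign(b))
})

test_that("BH control matches a brute-force step-up on random p-vectors", {
  set.seed(31)
  for (i in 1:300) {
    m <- sample(1:40, 1)
    p <- setNames(runif(m)^sample(1:3, 1), paste0("t", seq_len(m)))
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    got <- bh_fdr(p, q)
    expect_setequal(got$rejected, bh_oracle(p, q))
  }
  # monotone in q
  p <- setNames(runif(25), paste0("t", 1:25))
  ns <- vapply(c(0.01, 0.05, 0.1, 0.25, 0.5), function(q) bh_fdr(p, q)$n_rejected, 0)
  expect_true(all(diff(ns) >= 0))
  # edge cases
  expect_equal(bh_fdr(setNames(numeric(0), character(0)))$n_rejected, 0L)
  expect_equal(bh_fdr(setNames(rep(0.001, 10), letters[1:10]))$n_rejected, 10L)
})

test_that("Huber regression is exact on clean data and equals OLS below threshold", {
  set.seed(41)
  n <- 60
  df <- data.frame(
    moca = 0, x = rnorm(n), age = runif(n, 50, 89),
    sex = rbinom(n, 1, 0.5), group = sample(c("BA", "nHW"), n, TRUE),
    education = rnorm(n, 14), physical_activity = runif(n, 1, 20),
    diabetes = rbinom(n, 1, 0.2), hypertension = rbinom(n, 1, 0.4),
    high_cholesterol = rbinom(n, 1, 0.3), apoe4 = rbinom(n, 1, 0.3))
  lin <- 20 + 2 * df$x - 0.05 * df$age + 0.5 * df$sex
  # exactly noiseless: the fit is exact (scale collapses, coefficients stay)
  df$moca <- lin
  fit0 <- suppressWarnings(huber_regression(df, "x"))
  expect_equal(fit0$result$beta, 2, tolerance = 1e-8)

  # alternating tiny residuals: all below the Huber threshold after MAD
  # scaling, so every weight is 1 and the fit is ordinary least squares
  df$moca <- lin + rep(c(-0.1, 0.1), length.out = n)
  fit <- huber_regression(df, "x")
  expect_equal(fit$result$beta, 2, tolerance = 0.05)
  expect_equal(fit$result$per_percent_effect, fit$result$beta / 100)

  ols <- lm(moca ~ x + age + sex + I(group == "BA") + education +
              physical_activity + diabetes + hypertension + high_cholesterol +
              apoe4, data = df)
  expect_equal(fit$result$beta, unname(coef(ols)["x"]), tolerance = 1e-8)
})

test_that("Huber regression recovers planted effects and resists contamination", {
  bias_h <- bias_o <- numeric(10)
  covered <- logical(10)
  for (s in 1:10) {
    co <- make_cohort(200, 5, c(uwmc_001 = -1.5), intercept = 20,
                      noise_sd = 2, seed = 300 + s)
    df <- log_features(co)
    fit <- huber_regression(df, "uwmc_001")
    covered[s] <- abs(fit$result$beta - (-1.5)) < 3 * fit$result$se

    # same draws, 10% gross outliers added to the outcome
    dfc <- df
    out_idx <- withr::with_seed(900 + s, sample.int(nrow(dfc), 20))
    dfc$moca <- dfc$moca + ifelse(seq_len(nrow(dfc)) %in% out_idx, 15, 0)
    fit_h <- huber_regression(dfc, "uwmc_001")
    cov_terms <- paste(c("age", "sex", "I(group == 'BA')", "education",
                         "physical_activity", "diabetes", "hypertension",
                         "high_cholesterol", "apoe4"), collapse = " + ")
    fit_o <- lm(stats::as.formula(paste("moca ~ uwmc_001 +", cov_terms)), data = dfc)
    bias_h[s] <- abs(fit_h$result$beta - (-1.5))
    bias_o[s] <- abs(unname(coef(fit_o)["uwmc_001"]) - (-1.5))
  }
  expect_true(all(covered))
  expect_lt(mean(bias_h), mean(bias_o))
})

test_that("stratified and interaction models use the right rows and terms", {
  co <- make_cohort(240, 4, c(uwmc_002 = -2), noise_sd = 1, seed = 55)
  df <- log_features(co)
  full <- huber_regression(df, "uwmc_002")
  ba <- huber_regression(df, "uwmc_002", stratum = "BA")
  nhw <- huber_regression(df, "uwmc_002", stratum = "nHW")
  expect_equal(ba$result$n + nhw$result$n, full$result$n)
  expect_false("group" %in% tidy(ba)$term)
  expect_true("group" %in% tidy(full)$term)

  inter <- huber_regression(df, "uwmc_002", with_interaction = TRUE)
  expect_equal(inter$result$stratum, "interaction")
  expect_true(any(grepl(":group", tidy(inter)$term)))
  expect_error(huber_regression(df, "uwmc_002", stratum = "BA",
                                with_interaction = TRUE), "full sample")
  expect_error(huber_regression(df[1:8, ], "uwmc_002"), "too few")
})

test_that("the interaction model is fitted only on stratified disagreement", {
  co <- make_cohort(240, 4, c(uwmc_001 = -2), noise_sd = 1, seed = 77)
  df <- log_features(co)
  fdr_yes <- bh_fdr(c(uwmc_001 = 0.001), 0.05)
  fdr_no <- bh_fdr(c(uwmc_001 = 0.9), 0.05)
  expect_s3_class(conditional_interaction(df, "uwmc_001", fdr_yes, fdr_no),
                  "uwmc_huber")
  expect_null(conditional_interaction(df, "uwmc_001", fdr_yes, fdr_yes))
  expect_null(conditional_interaction(df, "uwmc_001", fdr_no, fdr_no))
})

test_that("stability selection is deterministic and order-invariant", {
  co <- make_cohort(120, 12, c(uwmc_003 = 1.2, uwmc_007 = 1.2),
                    effect_scale = "standardized", noise_sd = 1, seed = 61)
  df <- log_features(co)
  fs <- feature_names(df)
  s1 <- stability_select(df, fs, n_reps = 30, seed = 5)
  s2 <- stability_select(df, fs, n_reps = 30, seed = 5)
  expect_identical(s1$frequency, s2$frequency)

  perm <- rev(fs)
  s3 <- stability_select(df, perm, n_reps = 30, seed = 5)
  reordered <- s3$frequency[match(s1$frequency$feature, s3$frequency$feature), ]
  expect_equal(s1$frequency$frequency, reordered$frequency)

  # frequencies are multiples of 1/n_reps
  expect_true(all(abs(s1$frequency$frequency * 30 -
                        round(s1$frequency$frequency * 30)) < 1e-12))

  dfc <- df; dfc$uwmc_001 <- 0.3
  expect_warning(stability_select(dfc, fs, n_reps = 2, seed = 5), "constant")
})

test_that("Spearman validation behaves on monotone, reversed, and tied input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_validation(x, x^3)$rho, 1)
  expect_equal(spearman_validation(x, -x)$rho, -1)
  expect_error(spearman_validation(rep(1, 5), x), "constant")
  got <- spearman_validation(c(1, 2, 2, 3, 7), c(2, 1, 4, 4, 9))
  expect_equal(got$rho, unname(cor(rank(c(1, 2, 2, 3, 7)), rank(c(2, 1, 4, 4, 9)))))
})

test_that("lobar UWMC tracks lobar lesion volume across a phantom cohort", {
  lob_u <- lob_v <- numeric(30)
  for (i in 1:30) {
    frac <- (i - 1) / 30
    # vary lesion load: crossing fraction and bulk load grow together
    ph2 <- make_phantom(
      tibble::tibble(id = 1:2, name = c("ra", "rb"), lobe = "frontal",
                     hemisphere = c("L", "R"), center_x = c(8, 32),
                     center_y = 20, center_z = 10, radius = 5,
                     in_abeta_set = TRUE, in_tau_set = FALSE),
      tibble::tibble(a = 1L, b = 2L, n_streamlines = 5L,
                     target_uwmc = round(frac * 5) / 5),
      bundle_spread = 5, lesion_bulk_fraction = frac * 0.04, seed = 400 + i)
    counts <- count_connections(ph2$streamlines, ph2$labels, ph2$wmh)
    lob <- lobar_uwmc(counts, ph2$labels)
    lob_u[i] <- lob$uwmc[lob$lobe == "frontal"]
    vol <- lobar_wmh_volume(ph2$wmh, ph2$labels,
                            binary_mask(array(TRUE, dim(ph2$wmh$data)), ph2$wmh$affine))
    lob_v[i] <- sum(vol$wmh_mm3)
  }
  got <- spearman_validation(lob_u, lob_v)
  expect_gt(got$rho, 0.7)
})

test_that("group descriptives pick the right test and split at the median", {
  n <- 40
  df <- data.frame(group = rep(c("BA", "nHW"), each = n / 2),
                   age = rep(c(60, 61, 70, 71), n / 4),
                   apoe4 = rep(c(0, 1), n / 2))
  # identical distributions across groups: exact test p = 1
  out <- describe_groups(df, split = "group", variables = c("age", "apoe4"))
  expect_equal(out$p.value[out$variable == "apoe4"], 1)
  expect_equal(out$test[out$variable == "age"], "mann-whitney")

  # a value exactly at the median goes to the high group
  df2 <- data.frame(global_uwmc = c(0.1, 0.2, 0.3, 0.3, 0.9),
                    age = c(60, 61, 62, 63, 64))
  out2 <- describe_groups(df2, split = "global_uwmc_median", variables = "age")
  # median 0.3; both 0.3 values land in "high": split is 2 vs 3
  expect_match(out2$summary2, "62")

  # 2x2 (20,5;5,20): chi-square and Fisher vs textbook formulas
  tab <- matrix(c(20, 5, 5, 20), 2)
  df3 <- data.frame(group = rep(c("BA", "nHW"), times = c(25, 25)),
                    flag = rep(c(1, 0, 1, 0), times = c(20, 5, 5, 20)))
  out3 <- describe_groups(df3, split = "group", variables = "flag")
  x2 <- 50 * (20 * 20 - 5 * 5)^2 / (25 * 25 * 25 * 25)
  p_chi <- pchisq(x2, 1, lower.tail = FALSE)
  p_fis <- fisher.test(tab)$p.value
  expect_true(abs(out3$p.value - p_chi) < 1e-6 || abs(out3$p.value - p_fis) < 1e-6)
  expect_equal(out3$test, "chi-square")  # expected counts all 12.5

  expect_error(describe_groups(df3[df3$group == "BA", ], split = "group"),
               "non-empty")
})

test_that("the end-to-end cohort analysis recovers planted structure", {
  co <- make_cohort(250, 20, c(uwmc_004 = 1, uwmc_012 = 1),
                    effect_scale = "standardized", noise_sd = 1, seed = 83)
  res <- analyze_uwmc_cohort(co, feature_names(co), n_reps = 40, seed = 83)
  expect_setequal(res$selection$selected, c("uwmc_004", "uwmc_012"))
  expect_equal(nrow(res$results), 2)
  expect_true(all(res$results$fdr_full))
  # FDR flags must agree with a direct BH run on the same column
  redo <- bh_fdr(setNames(res$results$p_full, res$results$predictor), 0.05)
  expect_equal(res$results$predictor %in% redo$rejected, res$results$fdr_full)
  # interaction p present only where exactly one stratum rejected
  disagree <- xor(res$results$fdr_ba, res$results$fdr_nhw)
  expect_equal(!is.na(res$results$interaction_p), disagree)
})
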