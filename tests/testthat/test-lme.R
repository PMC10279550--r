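# Per-protein linear mixed models: exact limits, independent oracles,
# simulation recovery, and the feature-matrix assembly.

sim_lme_data <- function(n = 40, times = c(0, 0.5, 1), beta = c(1, -0.5),
                         psi = c(0.8, 0.3), rho = 0.2, sigma = 0.4,
                         seed = 1) {
  set.seed(seed)
  Psi <- matrix(c(psi[1]^2, rho * psi[1] * psi[2],
                  rho * psi[1] * psi[2], psi[2]^2), 2, 2)
  ch <- chol(Psi + diag(1e-12, 2))
  b <- matrix(rnorm(2 * n), n) %*% ch
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(patient_id = sprintf("P%03d", i), time_years = times,
               value = beta[1] + b[i, 1] + (beta[2] + b[i, 2]) * times +
                 rnorm(length(times), 0, sigma),
               stringsAsFactors = FALSE)
  }))
  list(df = df, Psi = Psi, beta = beta, sigma2 = sigma^2)
}

test_that("noiseless common-line data are fitted exactly", {
  df <- data.frame(patient_id = rep(sprintf("P%d", 1:5), each = 3),
                   time_years = rep(c(0, 0.5, 1), 5))
  df$value <- 1 + 2 * df$time_years
  fit <- fit_lme(df)
  expect_equal(unname(fit$beta), c(1, 2), tolerance = 1e-9)
  expect_lt(fit$sigma2, 1e-12)
  feats <- predict_features(fit)
  expect_lt(max(abs(feats[, "intercept"] - 1)), 1e-8)
  expect_lt(max(abs(feats[, "slope"] - 2)), 1e-8)
})

test_that("predictions equal the Henderson mixed-model-equations oracle", {
  # balanced design; the oracle solves the dense GLS/BLUP system at the
  # fitted variance components
  sim <- sim_lme_data(n = 30, seed = 7)
  fit <- fit_lme(sim$df)
  orc <- henderson_oracle(sim$df$patient_id, sim$df$time_years, sim$df$value,
                          fit$Psi, fit$sigma2)
  expect_lt(max(abs(unname(fit$beta) - orc$beta)), 1e-6)
  feats <- predict_features(fit)
  pred_oracle <- cbind(orc$beta[1] + orc$blup[, "b0"],
                       orc$beta[2] + orc$blup[, "b1"])
  expect_lt(max(abs(unname(feats) - unname(pred_oracle))), 1e-6)
})

test_that("fits agree with lme4 on balanced and unbalanced data", {
  skip_if_not_installed("lme4")
  sim <- sim_lme_data(n = 50, seed = 3)
  df <- sim$df
  # unbalance: drop a third visit for a fifth of the patients
  drop_idx <- with(df, patient_id %in% sprintf("P%03d", 1:10) & time_years == 1)
  df <- df[!drop_idx, ]
  fit <- fit_lme(df)
  lf <- lme4::lmer(value ~ time_years + (time_years | patient_id), data = df,
                   REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-4)
  expect_equal(fit$sigma2, sigma(lf)^2, tolerance = 1e-3)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$Psi[1, 1], vc$vcov[1], tolerance = 1e-2)
  expect_equal(fit$Psi[2, 2], vc$vcov[2], tolerance = 1e-2)
  blup <- stats::coef(lf)$patient_id
  feats <- predict_features(fit)
  ord <- match(rownames(feats), rownames(blup))
  expect_lt(max(abs(feats[, "intercept"] - blup[ord, "(Intercept)"])), 1e-3)
  expect_lt(max(abs(feats[, "slope"] - blup[ord, "time_years"])), 1e-3)
})

test_that("REML criterion at the optimum is no worse than at the start", {
  sim <- sim_lme_data(n = 20, seed = 9)
  ds <- protraj:::.lme_design_stats(sim$df$patient_id, sim$df$time_years)
  y <- sim$df$value
  idx <- ds$idx
  Sy <- as.numeric(rowsum(y, idx)); Sty <- as.numeric(rowsum(y * ds$time, idx))
  Syy <- as.numeric(rowsum(y^2, idx))
  fit <- protraj:::.lme_fit_stats(ds, Sy, Sty, Syy)
  g0 <- protraj:::.gamma_from_theta(c(log(0.7), 0, log(0.35)))
  crit0 <- protraj:::.lme_profile(ds, Sy, Sty, Syy, g0[1], g0[2], g0[3])$crit
  expect_lte(fit$crit, crit0 + 1e-8)
})

test_that("fixed effects are recovered within Monte-Carlo error with calibrated Wald intervals", {
  # 100 simulated proteins, 3 visits each; also Wald coverage for the slope
  reps <- 100
  b0 <- b1 <- se1 <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- sim_lme_data(n = 60, seed = 100 + r)
    fit <- fit_lme(sim$df)
    b0[r] <- fit$beta[1]; b1[r] <- fit$beta[2]; se1[r] <- fit$beta_se[2]
  }
  expect_lt(abs(mean(b0) - 1), 3 * sd(b0) / sqrt(reps))
  expect_lt(abs(mean(b1) - (-0.5)), 3 * sd(b1) / sqrt(reps))
  coverage <- mean(abs(b1 - (-0.5)) <= 1.96 * se1)
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.99)
})

test_that("single-observation patients shrink toward the fixed line", {
  sim <- sim_lme_data(n = 30, seed = 21)
  one_obs <- data.frame(patient_id = "PX", time_years = 0.5, value = 10,
                        stringsAsFactors = FALSE)
  df <- rbind(sim$df, one_obs)
  fit <- fit_lme(df)
  feats <- predict_features(fit)
  # the lone extreme observation is pulled well toward the population line
  pred_own <- feats["PX", "intercept"] + feats["PX", "slope"] * 0.5
  pop <- fit$beta[1] + fit$beta[2] * 0.5
  expect_lt(abs(pred_own - pop), abs(10 - pop))
  # intercept-only models give every patient the fixed slope
  df2 <- sim_lme_data(n = 25, psi = c(0.8, 0), rho = 0, sigma = 0.3,
                      seed = 33)$df
  fit2 <- fit_lme(df2)
  if (fit2$model_form == "intercept_only")
    expect_true(all(abs(predict_features(fit2)[, "slope"] - fit2$beta[2]) < 1e-10))
})

test_that("degenerate inputs are flagged", {
  df <- data.frame(patient_id = c("A", "A", "B"), time_years = c(0, 1, 0),
                   value = c(5, 5, 5))
  fit <- fit_lme(df)
  expect_equal(fit$model_form, "degenerate")
  expect_true(all(predict_features(fit)[, "intercept"] == 5))
  expect_error(fit_lme(df[1:2, ]), "at least 3")
})

test_that("the repeated-mode feature matrix is standardized and equivariant", {
  coh <- generate_cohort(small_cohort(n = 10, P = 4, seed = 17))
  std <- log_zscore(select_samples(coh$long, coh$outcomes))
  fits <- fit_lme_all(std)
  feat <- assemble_feature_matrix(fits, "repeated")
  expect_equal(dim(feat), c(10L, 8L))
  expect_lt(max(abs(colMeans(feat))), 1e-9)
  expect_lt(max(abs(apply(feat, 2, sd) - 1)), 1e-9)
})

test_that("single-visit modes pick the right samples", {
  coh <- generate_cohort(small_cohort(n = 15, P = 3, seed = 19,
                                      baseline_hazard = 0.4))
  sel <- select_samples(coh$long, coh$outcomes)
  std <- log_zscore(sel)
  base <- assemble_feature_matrix(std, "baseline")
  # baseline mode equals the standardized baseline rows exactly
  bl_rows <- std$samples$time_years == 0
  expect_equal(unname(base[std$samples$patient_id[bl_rows], , drop = FALSE]),
               unname(std$values[bl_rows, , drop = FALSE]))
  second <- assemble_feature_matrix(std, "second")
  per <- table(std$samples$patient_id)
  expect_setequal(attr(second, "dropped"), names(per)[per < 2])
  last <- assemble_feature_matrix(std, "last")
  expect_equal(nrow(last), 15L)
})

test_that("feature matrix is invariant to the upstream log base", {
  # double standardization makes natural log and log10 equivalent
  coh <- generate_cohort(small_cohort(n = 12, P = 3, seed = 23))
  sel <- select_samples(coh$long, coh$outcomes)
  std_e <- log_zscore(sel)
  sel10 <- sel
  sel10$rfu <- exp(log10(sel$rfu))  # ln of this equals log10 of original
  std_10 <- log_zscore(sel10)
  f_e <- assemble_feature_matrix(fit_lme_all(std_e), "repeated")
  f_10 <- assemble_feature_matrix(fit_lme_all(std_10), "repeated")
  expect_lt(max(abs(f_e - f_10)), 1e-8)
})
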