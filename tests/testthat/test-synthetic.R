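# Synthetic cohort generator and the adjusted Rand index.

test_that("identical config and seed give identical cohorts", {
  cfg <- small_cohort(n = 30, P = 8, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$long, b$long)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$truth, b$truth)
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(mixing = c(0.5, 0.6), k_true = 2), "sum to 1")
  expect_error(cohort_config(k_true = 2, mixing = c(0.5, 0.5),
                             log_hr = c(0.1, 0)), "log_hr\\[1\\]")
  expect_error(cohort_config(subset_sizes = c(10, 10), n_proteins = 30,
                             n_subsets = 2), "sum to n_proteins")
  expect_error(cohort_config(resid_sd = -1), "resid_sd")
  expect_error(cohort_config(k_true = 3, mixing = rep(1 / 3, 3),
                             intercept_effects = matrix(0, 2, 2)),
               "n_subsets x k_true")
})

test_that("every patient has a baseline visit and positive RFU", {
  coh <- generate_cohort(small_cohort(n = 40, P = 5, seed = 2))
  expect_silent(validate_long_protein_table(coh$long))
  expect_true(all(coh$long$rfu > 0))
  t0 <- tapply(coh$long$time_years, coh$long$patient_id, min)
  expect_true(all(t0 == 0))
})

test_that("null hazard ratios give similar event rates across subphenotypes", {
  # 200 replicates of a small cohort under log_hr = 0: per-subphenotype event
  # rates should agree within Monte-Carlo error
  rates <- matrix(NA_real_, 200, 2)
  for (r in 1:200) {
    cfg <- cohort_config(n_patients = 40, n_proteins = 1, k_true = 2,
                         mixing = c(0.5, 0.5), n_subsets = 1,
                         intercept_effects = matrix(0, 1, 2),
                         slope_effects = matrix(0, 1, 2),
                         log_hr = c(0, 0), baseline_hazard = 0.3, seed = r)
    coh <- generate_cohort(cfg)
    g <- coh$truth$patient[coh$outcomes$patient_id]
    rates[r, ] <- tapply(coh$outcomes$event, g, mean)[c("1", "2")]
  }
  diffs <- rates[, 1] - rates[, 2]
  mc_se <- sd(diffs, na.rm = TRUE) / sqrt(sum(!is.na(diffs)))
  expect_lt(abs(mean(diffs, na.rm = TRUE)), 3 * mc_se + 1e-12)
})

test_that("raising a subphenotype's log hazard raises its event count", {
  # hazard monotonicity checked over 200 replicates
  tot0 <- tot1 <- 0
  for (r in 1:200) {
    mk <- function(lhr, seed) {
      cfg <- cohort_config(n_patients = 30, n_proteins = 1, k_true = 2,
                           mixing = c(0.5, 0.5), n_subsets = 1,
                           intercept_effects = matrix(0, 1, 2),
                           slope_effects = matrix(0, 1, 2),
                           log_hr = c(0, lhr), baseline_hazard = 0.2,
                           seed = seed)
      coh <- generate_cohort(cfg)
      g <- coh$truth$patient[coh$outcomes$patient_id]
      sum(coh$outcomes$event[g == 2])
    }
    tot0 <- tot0 + mk(0, r)
    tot1 <- tot1 + mk(1.5, r)
  }
  expect_gt(tot1, tot0)
})

test_that("adjusted Rand index matches hand-computed values", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1.0)
  # permutation of label names leaves ARI at 1
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(7, 7, 3, 3)), 1.0)
  # all-ones 2x2 contingency: ARI = -0.5 by the adjustment formula
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(42)
  for (r in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("a structureless generator yields near-zero cluster recovery", {
  # all subphenotypes share identical effect profiles: downstream recovery
  # must be at chance level (|ARI| <= 0.05 at n = 300)
  cfg <- cohort_config(n_patients = 300, n_proteins = 40, k_true = 4,
                       intercept_effects = matrix(1, 4, 4),
                       slope_effects = matrix(0.2, 4, 4),
                       baseline_hazard = 1e-4, log_hr = rep(0, 4),
                       seed = 88)
  coh <- generate_cohort(cfg)
  fit <- protraj(coh$long, coh$outcomes, k = 4, R_stab = 0L, seed = 3)
  ari <- adjusted_rand_index(cluster_labels(fit),
                             coh$truth$patient[names(cluster_labels(fit))])
  expect_lt(abs(ari), 0.05)
})

test_that("noise-free generation is recovered exactly by the trajectory models", {
  # resid_sd -> 0 and no random effects: per-patient regression lines equal
  # the configured subset x subphenotype means
  eff_i <- matrix(c(1, -1, 0.5, -0.5), 2, 2)
  eff_s <- matrix(c(0.3, -0.3, 0.1, -0.1), 2, 2)
  cfg <- cohort_config(n_patients = 20, n_proteins = 4, k_true = 2,
                       mixing = c(0.5, 0.5), n_subsets = 2,
                       intercept_effects = eff_i, slope_effects = eff_s,
                       re_sd_intercept = 0, re_sd_slope = 0,
                       resid_sd = 1e-12, baseline_hazard = 1e-4,
                       log_hr = c(0, 0), seed = 4)
  coh <- generate_cohort(cfg)
  g <- coh$truth$patient
  subset_of <- coh$truth$protein_subset
  # regress the latent log-values directly (no standardization)
  for (p in names(subset_of)[c(1, 3)]) {
    sub <- coh$long[coh$long$seq_id == p, ]
    sub$value <- log(sub$rfu / 1000)
    fit <- fit_lme(sub, protein = p)
    feats <- predict_features(fit)
    expect_lt(max(abs(feats[, "intercept"] -
                        eff_i[subset_of[[p]], g[rownames(feats)]])), 1e-8)
    expect_lt(max(abs(feats[, "slope"] -
                        eff_s[subset_of[[p]], g[rownames(feats)]])), 1e-8)
  }
})

test_that("sample selection keeps 1-3 samples per generated patient", {
  coh <- generate_cohort(small_cohort(n = 80, P = 3, seed = 9,
                                      baseline_hazard = 0.5))
  sel <- select_samples(coh$long, coh$outcomes)
  per <- table(unique(sel[, c("patient_id", "sample_id")])$patient_id)
  expect_true(all(per >= 1 & per <= 3))
  expect_equal(sort(unique(sel$patient_id)), sort(coh$outcomes$patient_id))
})
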