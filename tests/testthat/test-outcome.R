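# Clinical comparisons, model-3 covariate selection, Cox fitting, Harrell's
# C, optimism correction, Kaplan-Meier/log-rank.

test_that("2x2 chi-square matches the hand formula and small cells use Fisher", {
  # [[10,20],[20,10]]: chi2 = 60*(10*10-20*20)^2 / 30^4 = 20/3
  x <- rep(c(0, 1), times = c(30, 30))
  g <- c(rep(1, 10), rep(2, 20), rep(1, 20), rep(2, 10))
  cl <- data.frame(patient_id = sprintf("P%02d", 1:60), v = x,
                   stringsAsFactors = FALSE)
  attr(cl, "types") <- c(v = "binary")
  labs <- setNames(g, cl$patient_id)
  cc <- compare_clinical(cl, labs)
  expect_equal(cc$table$test, "chi_square")
  expect_equal(cc$table$statistic, 60 * (10 * 10 - 20 * 20)^2 / 30^4,
               tolerance = 1e-12)
  # expected cell of 2 triggers Fisher
  cl2 <- data.frame(patient_id = sprintf("Q%02d", 1:20),
                    v = c(rep(1, 2), rep(0, 8), rep(1, 2), rep(0, 8)),
                    stringsAsFactors = FALSE)
  attr(cl2, "types") <- c(v = "binary")
  labs2 <- setNames(rep(1:2, each = 10), cl2$patient_id)
  cc2 <- compare_clinical(cl2, labs2)
  expect_equal(cc2$table$test, "fisher_exact")
})

test_that("null clinical comparisons give approximately uniform p-values", {
  set.seed(44)
  ps <- numeric(400)
  for (r in seq_along(ps)) {
    cl <- data.frame(patient_id = sprintf("P%03d", 1:60), v = rnorm(60),
                     stringsAsFactors = FALSE)
    attr(cl, "types") <- c(v = "numeric")
    labs <- setNames(sample(rep(1:3, each = 20)), cl$patient_id)
    ps[r] <- compare_clinical(cl, labs)$table$p
  }
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("constant variables are skipped with a record", {
  cl <- data.frame(patient_id = c("A", "B"), v = c(1, 1),
                   stringsAsFactors = FALSE)
  attr(cl, "types") <- c(v = "binary")
  cc <- compare_clinical(cl, setNames(1:2, c("A", "B")))
  expect_equal(cc$skipped, "v")
})

test_that("model-3 selection keeps truly associated covariates plus the forced trio", {
  hits <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 400
    ev <- rbinom(n, 1, 0.4)
    cl <- data.frame(patient_id = sprintf("P%03d", 1:n),
                     age = rnorm(n, 64, 9), sex = rbinom(n, 1, 0.7),
                     egfr = rnorm(n, 60, 15),
                     sbp = rnorm(n, 115 + 1 * 14 * ev, 14),  # 1 SD effect
                     noise = rnorm(n), stringsAsFactors = FALSE)
    attr(cl, "types") <- c(age = "numeric", sex = "binary", egfr = "numeric",
                           sbp = "numeric", noise = "numeric")
    out <- data.frame(patient_id = cl$patient_id,
                      time_to_event_years = rexp(n, 0.3) + 0.01, event = ev == 1,
                      stringsAsFactors = FALSE)
    sel <- select_model3_covariates(cl, out, seed = s)
    if (setequal(sel, c("age", "sex", "egfr", "sbp"))) hits <- hits + 1
  }
  expect_gte(hits, 9)
  # nothing associated: forced trio only
  set.seed(9)
  n <- 120
  cl0 <- data.frame(patient_id = sprintf("P%03d", 1:n), age = rnorm(n),
                    sex = rbinom(n, 1, 0.5), egfr = rnorm(n),
                    stringsAsFactors = FALSE)
  attr(cl0, "types") <- c(age = "numeric", sex = "binary", egfr = "numeric")
  out0 <- data.frame(patient_id = cl0$patient_id,
                     time_to_event_years = rexp(n, 0.3) + 0.01,
                     event = rbinom(n, 1, 0.5) == 1, stringsAsFactors = FALSE)
  expect_setequal(select_model3_covariates(cl0, out0, seed = 2),
                  c("age", "sex", "egfr"))
})

test_that("the toy Cox instance has the analytic solution beta = ln sqrt 2", {
  time <- c(1, 2, 3); event <- c(1, 1, 1)
  X <- matrix(c(0, 1, 0), ncol = 1, dimnames = list(NULL, "z"))
  fit <- fit_cox(X, time, event)
  expect_equal(unname(fit$coef), log(sqrt(2)), tolerance = 1e-6)
  expect_equal(unname(fit$hr), sqrt(2), tolerance = 1e-5)
  # grid-search oracle on the Efron partial likelihood agrees
  grid <- seq(-1, 1, by = 1e-4)
  ll <- vapply(grid, oracle_cox_loglik, 0, x = c(0, 1, 0), time = time,
               event = event)
  expect_equal(unname(fit$coef), grid[which.max(ll)], tolerance = 2e-4)
})

test_that("Cox fits agree with survival::coxph (Efron ties)", {
  set.seed(12)
  n <- 150
  X <- cbind(z1 = rnorm(n), z2 = rbinom(n, 1, 0.4))
  lp <- 0.7 * X[, 1] - 0.4 * X[, 2]
  time <- round(rexp(n, exp(lp) * 0.3), 2) + 0.01  # rounding creates ties
  event <- rbinom(n, 1, 0.7) == 1
  fit <- fit_cox(X, time, event)
  cph <- survival::coxph(survival::Surv(time, event) ~ X, ties = "efron")
  expect_equal(unname(fit$coef), unname(coef(cph)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cph)))), tolerance = 1e-6)
  expect_equal(fit$loglik, cph$loglik[2], tolerance = 1e-8)
  expect_equal(fit$AIC, stats::AIC(cph), tolerance = 1e-6)
})

test_that("null covariates are estimated near zero over replicates", {
  set.seed(5)
  reps <- 200
  betas <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 300
    X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "z"))
    time <- rexp(n, 0.3)
    event <- rbinom(n, 1, 0.7) == 1
    betas[r] <- fit_cox(X, time, event)$coef
  }
  expect_lt(abs(mean(betas)), 3 * sd(betas) / sqrt(reps))
})

test_that("degenerate Cox inputs raise the documented errors", {
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1)
  Xd <- cbind(a = c(0, 1, 0, 1), b = c(0, 1, 0, 1))
  expect_error(fit_cox(Xd, time, event), "singular|collinear")
  expect_error(fit_cox(cbind(a = rep(1, 4)), time, event), "constant")
  # perfect separation: the covariate orders failures exactly
  Xs <- cbind(a = c(4, 3, 2, 1))
  expect_error(fit_cox(Xs, time, event), "separation|monotone")
})

test_that("Harrell's C matches the exhaustive pair-enumeration oracle", {
  expect_equal(harrell_c(-c(1, 2, 3, 4), c(1, 2, 3, 4), rep(TRUE, 4)), 1.0)
  expect_equal(harrell_c(rep(0, 4), c(1, 2, 3, 4), rep(TRUE, 4)), 0.5)
  # the n = 4 censored instance, enumerated by brute force
  time <- c(1, 2, 3, 4); event <- c(1, 1, 0, 1); risk <- c(4, 3, 2, 1)
  expect_equal(harrell_c(risk, time, event),
               oracle_harrell(risk, time, event))
  set.seed(31)
  for (r in 1:15) {
    n <- 25
    risk <- sample(1:5, n, replace = TRUE)
    time <- sample(1:8, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6) == 1
    if (!any(event)) next
    expect_equal(harrell_c(risk, time, event),
                 oracle_harrell(risk, time, event))
  }
  expect_error(harrell_c(c(1, 2), c(5, 5), c(FALSE, FALSE)), "usable")
})

test_that("Harrell's C is invariant under monotone transforms of risk", {
  set.seed(8)
  n <- 60
  risk <- rnorm(n); time <- rexp(n, 0.5); event <- rbinom(n, 1, 0.6) == 1
  c1 <- harrell_c(risk, time, event)
  expect_equal(harrell_c(exp(risk), time, event), c1)
  expect_equal(harrell_c(rank(risk), time, event), c1)
})

test_that("optimism correction is reproducible and bounded by the apparent C", {
  set.seed(77)
  n <- 80
  X <- cbind(z = rnorm(n))
  time <- rexp(n, exp(0.8 * X[, 1]) * 0.3)
  event <- rbinom(n, 1, 0.8) == 1
  a <- optimism_corrected_c(X, time, event, B = 1, seed = 4)
  b <- optimism_corrected_c(X, time, event, B = 1, seed = 4)
  expect_identical(a, b)
  # with pure-noise covariates the model must overfit: positive optimism
  set.seed(78)
  Xn <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  tn <- rexp(n, 0.3); en <- rbinom(n, 1, 0.8) == 1
  cn <- optimism_corrected_c(Xn, tn, en, B = 30, seed = 4)
  expect_gt(cn$apparent, 0.5)
  expect_lt(cn$corrected, cn$apparent)
})

test_that("Kaplan-Meier steps and log-rank match the textbook cases", {
  # 4 uncensored events: survival drops 0.75, 0.5, 0.25, 0
  fit <- survival::survfit(survival::Surv(c(1, 2, 3, 4), rep(1, 4)) ~ 1)
  expect_equal(fit$surv, c(0.75, 0.5, 0.25, 0))
  # identical groups: log-rank statistic 0
  km <- kaplan_meier_logrank(c(1, 2, 3, 1, 2, 3), rep(1, 6),
                             rep(1:2, each = 3))
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$p, 1, tolerance = 1e-12)
  expect_error(kaplan_meier_logrank(c(1, 2), c(1, 1), c(1, 1)), "2 non-empty")
})

test_that("log-rank detects a strong hazard ratio reliably", {
  # two-group exponential with HR 3: p < 0.001 in nearly all replicates
  hits <- 0
  for (r in 1:40) {
    set.seed(600 + r)
    n <- 150
    g <- rep(1:2, each = n / 2)
    time <- rexp(n, 0.2 * ifelse(g == 2, 3, 1))
    cens <- pmin(time, 3)
    km <- kaplan_meier_logrank(cens, time <= 3, g)
    if (km$p < 0.001) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("the four adjustment levels nest as specified", {
  coh <- generate_cohort(small_cohort(n = 150, P = 4, seed = 55, k = 2,
                                      baseline_hazard = 0.3))
  fitp <- protraj(coh$long, coh$outcomes, k = 2, B_boot = 1, R_stab = 0,
                  seed = 2)
  cx <- cox_adjustment_levels(cluster_labels(fitp), coh$clinical,
                              coh$outcomes, B = 10, seed = 3)
  expect_named(cx$fits, c("1", "2", "3", "4"))
  # level 1: only subphenotype dummies
  expect_true(all(grepl("^subpheno", names(cx$fits[["1"]]$coef))))
  # level 2 adds exactly the forced trio
  expect_setequal(setdiff(names(cx$fits[["2"]]$coef),
                          names(cx$fits[["1"]]$coef)),
                  c("age", "sex", "egfr"))
  # level 3 contains level 2's covariates; level 4 adds log NT-proBNP
  expect_true(all(names(cx$fits[["2"]]$coef) %in% names(cx$fits[["3"]]$coef)))
  expect_setequal(setdiff(names(cx$fits[["4"]]$coef),
                          names(cx$fits[["3"]]$coef)), "log_ntprobnp")
  expect_true(all(c("AIC", "BIC", "corrected_c") %in% names(cx$summary)))
})
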