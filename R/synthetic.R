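#' Configuration for a synthetic longitudinal proteomic cohort
#'
#' Defines a cohort of heart-failure-like patients with `k_true` latent
#' subphenotypes, `n_proteins` aptamer-measured proteins organised into
#' `n_subsets` protein subsets, trimonthly visits, and exponential
#' time-to-event outcomes with subphenotype-specific hazard ratios.
#'
#' The defaults describe the study conditions the package is exercised under:
#' 400 patients, 500 proteins, four subphenotypes and four protein subsets,
#' a standardized between-subphenotype effect of 1.5 on each subset's
#' intercepts (0.75 per year on slopes), visits every 0.25 years with a small
#' scheduling jitter, and hazard ratios of 1, 3.43, 2.88 and 1 versus
#' subphenotype 1.
#'
#' @param n_patients number of patients.
#' @param n_proteins number of measured proteins (one aptamer each).
#' @param k_true number of latent subphenotypes.
#' @param mixing probability vector of length `k_true`; must sum to 1.
#' @param n_subsets number of protein subsets.
#' @param subset_sizes integer vector summing to `n_proteins`; defaults to a
#'   near-even split.
#' @param intercept_effects `n_subsets x k_true` matrix of mean standardized
#'   baseline levels per (subset, subphenotype).
#' @param slope_effects `n_subsets x k_true` matrix of mean slopes per year.
#' @param re_sd_intercept,re_sd_slope between-patient SDs of the random
#'   intercept and slope (per protein).
#' @param resid_sd residual SD of a single measurement.
#' @param visit_interval_years scheduled visit spacing (years).
#' @param visit_jitter_sd SD of the Gaussian jitter on scheduled visit times,
#'   truncated so visit times stay strictly increasing.
#' @param max_followup_years maximum length of the visit schedule.
#' @param log_hr vector of length `k_true` of log hazard ratios versus
#'   subphenotype 1; the first entry must be 0.
#' @param baseline_hazard constant baseline hazard (events per year).
#' @param admin_censor_years administrative censoring time.
#' @param seed integer seed; the same configuration and seed always produce
#'   byte-identical cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 400L,
                          n_proteins = 500L,
                          k_true = 4L,
                          mixing = rep(1 / k_true, k_true),
                          n_subsets = 4L,
                          subset_sizes = NULL,
                          intercept_effects = NULL,
                          slope_effects = NULL,
                          re_sd_intercept = 1,
                          re_sd_slope = 0.25,
                          resid_sd = 0.3,
                          visit_interval_years = 0.25,
                          visit_jitter_sd = 0.02,
                          max_followup_years = 2.5,
                          log_hr = NULL,
                          baseline_hazard = 0.08,
                          admin_censor_years = 2.5,
                          seed = 1L) {
  n_patients <- as.integer(n_patients)
  n_proteins <- as.integer(n_proteins)
  k_true <- as.integer(k_true)
  n_subsets <- as.integer(n_subsets)
  stopifnot(n_patients >= 2L, n_proteins >= 1L, k_true >= 1L, n_subsets >= 1L)

  if (length(mixing) != k_true)
    stop("'mixing' must have length k_true", call. = FALSE)
  if (abs(sum(mixing) - 1) > 1e-9)
    stop("'mixing' must sum to 1 (within 1e-9)", call. = FALSE)
  if (any(mixing < 0)) stop("'mixing' must be nonnegative", call. = FALSE)

  if (is.null(subset_sizes)) {
    base <- n_proteins %/% n_subsets
    subset_sizes <- rep(base, n_subsets)
    rem <- n_proteins - base * n_subsets
    if (rem > 0) subset_sizes[seq_len(rem)] <- subset_sizes[seq_len(rem)] + 1L
  }
  subset_sizes <- as.integer(subset_sizes)
  if (length(subset_sizes) != n_subsets || sum(subset_sizes) != n_proteins)
    stop("'subset_sizes' must have length n_subsets and sum to n_proteins",
         call. = FALSE)

  if (is.null(intercept_effects)) {
    intercept_effects <- matrix(0, n_subsets, k_true)
    for (g in seq_len(k_true))
      intercept_effects[((g - 1L) %% n_subsets) + 1L, g] <- 1.5
  }
  if (is.null(slope_effects)) {
    slope_effects <- matrix(0, n_subsets, k_true)
    for (g in seq_len(k_true))
      slope_effects[(g %% n_subsets) + 1L, g] <- 0.75
  }
  intercept_effects <- as.matrix(intercept_effects)
  slope_effects <- as.matrix(slope_effects)
  if (!all(dim(intercept_effects) == c(n_subsets, k_true)) ||
      !all(dim(slope_effects) == c(n_subsets, k_true)))
    stop("effect matrices must be n_subsets x k_true", call. = FALSE)

  if (is.null(log_hr)) {
    log_hr <- if (k_true == 4L) log(c(1, 3.43, 2.88, 1)) else rep(0, k_true)
  }
  if (length(log_hr) != k_true)
    stop("'log_hr' must have length k_true", call. = FALSE)
  if (abs(log_hr[1L]) > 0)
    stop("log_hr[1] must be 0 (subphenotype 1 is the reference)", call. = FALSE)

  for (nm in c("re_sd_intercept", "re_sd_slope", "visit_jitter_sd"))
    .assert_scalar_num(get(nm), nm, min = 0)
  for (nm in c("resid_sd", "visit_interval_years", "max_followup_years",
               "baseline_hazard", "admin_censor_years"))
    .assert_scalar_num(get(nm), nm, min = 0, strict = TRUE)

  structure(list(
    n_patients = n_patients, n_proteins = n_proteins, k_true = k_true,
    mixing = as.numeric(mixing), n_subsets = n_subsets,
    subset_sizes = subset_sizes,
    intercept_effects = intercept_effects, slope_effects = slope_effects,
    re_sd_intercept = re_sd_intercept, re_sd_slope = re_sd_slope,
    resid_sd = resid_sd, visit_interval_years = visit_interval_years,
    visit_jitter_sd = visit_jitter_sd,
    max_followup_years = max_followup_years,
    log_hr = as.numeric(log_hr), baseline_hazard = baseline_hazard,
    admin_censor_years = admin_censor_years, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d patients, %d proteins, %d subphenotypes, %d protein subsets\n",
              x$n_patients, x$n_proteins, x$k_true, x$n_subsets))
  cat(sprintf("  visits every %.2f yr (jitter SD %.3f), censoring at %.2f yr\n",
              x$visit_interval_years, x$visit_jitter_sd, x$admin_censor_years))
  cat(sprintf("  baseline hazard %.3f/yr, HR vs subphenotype 1: %s\n",
              x$baseline_hazard,
              paste(sprintf("%.2f", exp(x$log_hr)), collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic longitudinal proteomic cohort
#'
#' Draws a cohort from a [cohort_config()]: each patient belongs to a latent
#' subphenotype, has trimonthly visits from baseline until the earlier of the
#' event, censoring, or the follow-up limit, and every protein follows
#' `intercept + slope * time` on the standardized log scale with patient-level
#' random effects and residual noise. Event times are exponential with rate
#' `baseline_hazard * exp(log_hr[subphenotype])`. RFU readouts are emitted as
#' `exp(latent) * 1000` so the downstream log/Z-score path is nontrivial.
#'
#' @param config a [cohort_config()].
#' @return A list of class `protraj_cohort` with elements `long`
#'   (long-format protein table), `clinical`, `outcomes`, `annotation`,
#'   `truth` (latent labels and event/censoring times) and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("'config' must be a cohort_config", call. = FALSE)
  with_local_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  P <- cfg$n_proteins
  patient_id <- sprintf("P%04d", seq_len(n))
  seq_id <- sprintf("SL%04d", seq_len(P))
  subpheno <- as.integer(sample.int(cfg$k_true, n, replace = TRUE,
                                    prob = cfg$mixing))
  protein_subset <- rep(seq_len(cfg$n_subsets), times = cfg$subset_sizes)

  # survival outcome: exponential with subphenotype-specific hazard
  rate <- cfg$baseline_hazard * exp(cfg$log_hr[subpheno])
  true_event_time <- rexp(n, rate = rate)
  censor_time <- rep(cfg$admin_censor_years, n)
  time_obs <- pmin(true_event_time, censor_time)
  event <- true_event_time <= censor_time

  # visit schedule: baseline plus jittered trimonthly visits strictly before
  # the end of observation and the follow-up limit
  horizon <- pmin(time_obs, cfg$max_followup_years)
  visit_times <- vector("list", n)
  for (i in seq_len(n)) {
    times <- 0
    j <- 1L
    repeat {
      t_sched <- j * cfg$visit_interval_years
      if (t_sched >= horizon[i] + cfg$visit_interval_years) break
      t_j <- t_sched + rnorm(1L, 0, cfg$visit_jitter_sd)
      t_j <- max(t_j, times[length(times)] + 0.01)  # keep strictly increasing
      if (t_j < horizon[i]) times <- c(times, t_j)
      j <- j + 1L
      if (j > 1000L) break
    }
    visit_times[[i]] <- times
  }
  n_visits <- lengths(visit_times)
  v_patient <- rep(seq_len(n), n_visits)
  v_time <- unlist(visit_times, use.names = FALSE)
  v_index <- unlist(lapply(n_visits, seq_len), use.names = FALSE)
  sample_id <- sprintf("%s-V%02d", patient_id[v_patient], v_index)

  # latent standardized log values: subset/subphenotype means + random effects
  mu_int <- cfg$intercept_effects[protein_subset, subpheno, drop = FALSE]  # P x n
  mu_slo <- cfg$slope_effects[protein_subset, subpheno, drop = FALSE]
  A <- t(mu_int) + matrix(rnorm(n * P, 0, cfg$re_sd_intercept), n, P)  # n x P
  S <- t(mu_slo) + matrix(rnorm(n * P, 0, cfg$re_sd_slope), n, P)
  V <- length(v_time)
  latent <- A[v_patient, , drop = FALSE] +
    S[v_patient, , drop = FALSE] * v_time +
    matrix(rnorm(V * P, 0, cfg$resid_sd), V, P)
  rfu <- exp(latent) * 1000

  long <- data.frame(
    patient_id = rep(patient_id[v_patient], times = P),
    sample_id = rep(sample_id, times = P),
    time_years = rep(v_time, times = P),
    seq_id = rep(seq_id, each = V),
    rfu = as.vector(rfu),
    stringsAsFactors = FALSE
  )
  long <- long[order(long$patient_id, long$time_years, long$seq_id), ,
               drop = FALSE]
  rownames(long) <- NULL

  clinical <- .generate_clinical(patient_id, subpheno, cfg$k_true)

  outcomes <- data.frame(
    patient_id = patient_id,
    time_to_event_years = time_obs,
    event = event,
    stringsAsFactors = FALSE
  )

  annotation <- data.frame(
    seq_id = seq_id,
    target_id = sprintf("TGT%04d", seq_len(P)),
    is_human = TRUE,
    is_validated = TRUE,
    affinity_kd = round(runif(P, 0.05, 5), 4),
    stringsAsFactors = FALSE
  )

  truth <- list(
    patient = setNames(subpheno, patient_id),
    protein_subset = setNames(protein_subset, seq_id),
    true_event_time = setNames(true_event_time, patient_id),
    censor_time = setNames(censor_time, patient_id)
  )

  structure(list(long = long, clinical = clinical, outcomes = outcomes,
                 annotation = annotation, truth = truth, config = cfg),
            class = "protraj_cohort")
}

# Clinical covariates named after the adjustment set of the survival models
# (age, sex, eGFR, SBP, HF duration, NYHA class, atrial fibrillation, other
# arrhythmia, chronic renal failure) plus an NT-proBNP surrogate. Shifts per
# subphenotype loosely follow the ordering seen in heart-failure cohorts.
.generate_clinical <- function(patient_id, subpheno, k) {
  g <- subpheno
  age_shift <- rep_len(c(6, 4, -7, -5), k)[g]
  sbp_shift <- rep_len(c(9, -3, -5, 5), k)[g]
  egfr_shift <- rep_len(c(-4, -7, 8, 14), k)[g]
  nt_shift <- rep_len(c(-0.2, 0.6, -0.5, -0.4), k)[g]
  nyha_p <- rep_len(c(0.76, 0.59, 0.80, 0.84), k)[g]
  afib_p <- rep_len(c(0.39, 0.52, 0.20, 0.35), k)[g]
  arr_p <- rep_len(c(0.19, 0.41, 0.50, 0.49), k)[g]
  renal_p <- rep_len(c(0.45, 0.65, 0.36, 0.37), k)[g]

  n <- length(patient_id)
  df <- data.frame(
    patient_id = patient_id,
    age = round(rnorm(n, 64 + age_shift, 9), 1),
    sex = rbinom(n, 1L, 0.73),
    egfr = round(pmax(rnorm(n, 60 + egfr_shift, 15), 8), 1),
    sbp = round(rnorm(n, 115 + sbp_shift, 14), 0),
    hf_duration = round(rexp(n, 1 / 5), 2),
    ntprobnp = round(exp(rnorm(n, log(130) + nt_shift, 0.9)), 1),
    nyha_1_2 = rbinom(n, 1L, nyha_p),
    afib = rbinom(n, 1L, afib_p),
    other_arrhythmia = rbinom(n, 1L, arr_p),
    renal_failure = rbinom(n, 1L, renal_p),
    stringsAsFactors = FALSE
  )
  attr(df, "types") <- c(
    age = "numeric", sex = "binary", egfr = "numeric", sbp = "numeric",
    hf_duration = "numeric", ntprobnp = "numeric", nyha_1_2 = "binary",
    afib = "binary", other_arrhythmia = "binary", renal_failure = "binary"
  )
  df
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' permutation-invariant in both arguments. Used to compare recovered
#' subphenotypes with the generator's truth.
#'
#' @param labels_a,labels_b label vectors of equal length (>= 2).
#' @return The adjusted Rand index, a number in `[-1, 1]` (1 for identical
#'   partitions up to relabeling).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length", call. = FALSE)
  if (length(labels_a) < 2L)
    stop("need at least 2 items", call. = FALSE)
  tab <- table(labels_a, labels_b)
  comb2 <- function(x) sum(x * (x - 1) / 2)
  sij <- comb2(as.numeric(tab))
  si <- comb2(as.numeric(rowSums(tab)))
  sj <- comb2(as.numeric(colSums(tab)))
  ntot <- length(labels_a)
  expected <- si * sj / (ntot * (ntot - 1) / 2)
  maxi <- (si + sj) / 2
  if (abs(maxi - expected) < .Machine$double.eps) return(1)
  (sij - expected) / (maxi - expected)
}
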