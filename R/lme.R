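# Per-protein linear mixed models  y_ij = (b0 + u0_i) + (b1 + u1_i) t_ij + e_ij
# with (u0, u1) ~ N(0, Psi), e ~ N(0, sigma2), fitted by REML.
#
# The fitter works on per-patient sufficient statistics (n_i, sum t, sum t^2,
# sum y, sum t y, sum y^2). Writing Psi = sigma2 * Gamma and using the
# Woodbury identity, every per-patient quantity reduces to closed 2x2 forms
# that vectorize across patients, so one REML evaluation is O(n_patients)
# vector arithmetic. Gamma is parameterized by its log-Cholesky factor, which
# keeps it positive semi-definite. beta and sigma2 are profiled out.

# Per-patient design statistics shared by every protein measured on the same
# visit grid.
.lme_design_stats <- function(patient, time) {
  pid <- factor(patient, levels = unique(patient))
  idx <- as.integer(pid)
  n_i <- tabulate(idx)
  Tt <- as.numeric(rowsum(time, idx))
  Q <- as.numeric(rowsum(time^2, idx))
  list(idx = idx, levels = levels(pid), n = n_i, T = Tt, Q = Q,
       time = time, N = length(time))
}

# Profiled -2 REML criterion and GLS byproducts for Gamma = [[g11,g12],[g12,g22]].
.lme_profile <- function(ds, Sy, Sty, Syy, g11, g12, g22) {
  n <- ds$n; Tt <- ds$T; Q <- ds$Q
  C11 <- 1 + n * g11 + Tt * g12
  C12 <- n * g12 + Tt * g22
  C21 <- Tt * g11 + Q * g12
  C22 <- 1 + Tt * g12 + Q * g22
  detC <- C11 * C22 - C12 * C21
  if (any(detC <= 0) || any(!is.finite(detC))) return(NULL)

  # F = sum_i (I + W_i Gamma)^{-1} W_i  (2x2, symmetric)
  F11 <- sum((C22 * n - C12 * Tt) / detC)
  F12 <- sum((C22 * Tt - C12 * Q) / detC)
  F21 <- sum((-C21 * n + C11 * Tt) / detC)
  F22 <- sum((-C21 * Tt + C11 * Q) / detC)
  F12 <- (F12 + F21) / 2  # symmetric analytically

  # g = sum_i (I + W_i Gamma)^{-1} v_i,  v_i = (Sy_i, Sty_i)
  p1 <- (C22 * Sy - C12 * Sty) / detC
  p2 <- (-C21 * Sy + C11 * Sty) / detC
  gv1 <- sum(p1); gv2 <- sum(p2)

  # sum_i y' V*^{-1} y = Syy_i - v_i' Gamma (I + W_i Gamma)^{-1} v_i
  quad <- Sy * (g11 * p1 + g12 * p2) + Sty * (g12 * p1 + g22 * p2)
  yy <- sum(Syy) - sum(quad)

  detF <- F11 * F22 - F12^2
  if (detF <= 0 || !is.finite(detF)) return(NULL)
  beta0 <- (F22 * gv1 - F12 * gv2) / detF
  beta1 <- (-F12 * gv1 + F11 * gv2) / detF
  rss <- yy - (beta0 * gv1 + beta1 * gv2)
  rss <- max(rss, 0)
  Np <- ds$N - 2L
  sigma2 <- rss / Np
  crit <- if (sigma2 <= 0) -Inf else
    Np * log(sigma2) + sum(log(detC)) + log(detF)
  list(crit = crit, beta = c(beta0, beta1), sigma2 = sigma2,
       F11 = F11, F12 = F12, F22 = F22, detF = detF,
       detC = detC, C11 = C11, C12 = C12, C21 = C21, C22 = C22)
}

.gamma_from_theta <- function(theta) {
  l11 <- exp(theta[1L]); l21 <- theta[2L]; l22 <- exp(theta[3L])
  c(g11 = l11^2, g12 = l11 * l21, g22 = l21^2 + l22^2)
}

# Full random intercept+slope REML fit from sufficient statistics.
.lme_fit_stats <- function(ds, Sy, Sty, Syy, tol = 1e-8, maxit = 500L) {
  obj <- function(theta) {
    g <- .gamma_from_theta(theta)
    pr <- .lme_profile(ds, Sy, Sty, Syy, g[1L], g[2L], g[3L])
    if (is.null(pr) || !is.finite(pr$crit)) return(1e12)
    pr$crit
  }
  start <- c(log(0.7), 0, log(0.35))
  crit0 <- obj(start)
  op <- optim(start, obj, method = "L-BFGS-B",
              lower = c(-8, -60, -10), upper = c(8, 60, 8),
              control = list(maxit = maxit, factr = 1e5))
  # the optimizer must never end above its starting criterion
  stopifnot(op$value <= crit0 + 1e-6)
  g <- .gamma_from_theta(op$par)
  pr <- .lme_profile(ds, Sy, Sty, Syy, g[1L], g[2L], g[3L])
  list(theta = op$par, gamma = g, profile = pr, crit = op$value,
       converged = op$convergence == 0L)
}

# Random-intercept-only REML (fixed slope retained): Gamma = diag(gam, 0).
.lme_fit_intercept_only <- function(ds, Sy, Sty, Syy, tol = 1e-10) {
  obj <- function(ltheta) {
    gam <- exp(ltheta)
    pr <- .lme_profile(ds, Sy, Sty, Syy, gam, 0, 0)
    if (is.null(pr) || !is.finite(pr$crit)) return(1e12)
    pr$crit
  }
  op <- optimize(obj, interval = c(-25, 12), tol = tol)
  gam <- exp(op$minimum)
  pr <- .lme_profile(ds, Sy, Sty, Syy, gam, 0, 0)
  list(gamma = c(g11 = gam, g12 = 0, g22 = 0), profile = pr,
       crit = op$objective, converged = TRUE)
}

# BLUPs b_i = Gamma (I + W_i Gamma)^{-1} (v_i - W_i beta), vectorized.
.lme_blups <- function(ds, Sy, Sty, gamma, pr, beta) {
  n <- ds$n; Tt <- ds$T; Q <- ds$Q
  r1 <- Sy - (n * beta[1L] + Tt * beta[2L])
  r2 <- Sty - (Tt * beta[1L] + Q * beta[2L])
  q1 <- (pr$C22 * r1 - pr$C12 * r2) / pr$detC
  q2 <- (-pr$C21 * r1 + pr$C11 * r2) / pr$detC
  b0 <- gamma[1L] * q1 + gamma[2L] * q2
  b1 <- gamma[2L] * q1 + gamma[3L] * q2
  cbind(b0, b1)
}

# Per-patient OLS lines (exact features in the noise-free limit).
.patient_ols <- function(ds, Sy, Sty, beta) {
  n <- ds$n; Tt <- ds$T; Q <- ds$Q
  det <- n * Q - Tt^2
  ok <- det > 1e-12 & n >= 2L
  a <- rep(beta[1L], length(n)); s <- rep(beta[2L], length(n))
  a[ok] <- (Q[ok] * Sy[ok] - Tt[ok] * Sty[ok]) / det[ok]
  s[ok] <- (n[ok] * Sty[ok] - Tt[ok] * Sy[ok]) / det[ok]
  cbind(a, s)
}

.lme_fit_core <- function(ds, y, slope_var_floor = 1e-10) {
  idx <- ds$idx
  Sy <- as.numeric(rowsum(y, idx))
  Sty <- as.numeric(rowsum(y * ds$time, idx))
  Syy <- as.numeric(rowsum(y^2, idx))
  if (ds$N < 3L) stop("need at least 3 observations", call. = FALSE)

  if (var(y) < 1e-24) {  # all values identical: degenerate, constant features
    feat <- cbind(rep(y[1L], length(ds$n)), rep(0, length(ds$n)))
    return(list(beta = c(y[1L], 0), beta_se = c(0, 0),
                Psi = matrix(0, 2, 2), sigma2 = 0,
                reml_logLik = NA_real_, converged = TRUE,
                model_form = "degenerate", features = feat))
  }

  fit <- .lme_fit_stats(ds, Sy, Sty, Syy)
  pr <- fit$profile
  model_form <- "full"
  if (fit$gamma[3L] * pr$sigma2 < slope_var_floor) {
    fit <- .lme_fit_intercept_only(ds, Sy, Sty, Syy)
    pr <- fit$profile
    model_form <- "intercept_only"
  }
  sigma2 <- pr$sigma2
  gamma <- fit$gamma
  Psi <- sigma2 * matrix(c(gamma[1L], gamma[2L], gamma[2L], gamma[3L]), 2, 2)
  beta <- pr$beta
  # Wald SEs of the fixed effects from the GLS information, cov = sigma2 F^-1
  beta_se <- sqrt(pmax(sigma2 * c(pr$F22, pr$F11) / pr$detF, 0))

  if (sigma2 < 1e-12 * var(y)) {
    # essentially noise-free: BLUPs converge to each patient's own LS line
    feat <- .patient_ols(ds, Sy, Sty, beta)
  } else {
    b <- .lme_blups(ds, Sy, Sty, gamma, pr, beta)
    feat <- cbind(beta[1L] + b[, 1L], beta[2L] + b[, 2L])
  }
  reml_logLik <- -0.5 * (fit$crit + (ds$N - 2L) * (1 + log(2 * pi)))
  list(beta = beta, beta_se = beta_se, Psi = Psi, sigma2 = sigma2,
       reml_logLik = reml_logLik, converged = fit$converged,
       model_form = model_form, features = feat)
}

#' Fit a linear mixed-effects trajectory model for one protein
#'
#' Fits `value ~ time` with a patient-level random intercept and slope by
#' REML, with the random-effects covariance kept positive semi-definite
#' through a log-Cholesky parameterization and the fixed effects and residual
#' variance profiled out. If the estimated random-slope variance falls below
#' `1e-10`, the model is refitted with a random intercept only and flagged.
#'
#' @param data data frame with columns `patient_id`, `time_years`, `value`
#'   (standardized protein level).
#' @param protein optional protein identifier carried into the result.
#' @return An object of class `lme_fit`: fixed effects `beta` (intercept,
#'   slope per year) with Wald standard errors `beta_se`, random-effects
#'   covariance `Psi` (2x2), residual
#'   variance `sigma2`, `reml_logLik`, `converged`, `model_form`
#'   (`"full"`, `"intercept_only"` or `"degenerate"`), and `features`
#'   (per-patient predicted intercept and slope, `beta + BLUP`).
#' @export
fit_lme <- function(data, protein = NULL) {
  stopifnot(all(c("patient_id", "time_years", "value") %in% names(data)))
  if (any(data$time_years < 0)) stop("times must be nonnegative", call. = FALSE)
  if (nrow(data) < 3L)
    stop("need at least 3 observations in total", call. = FALSE)
  data <- data[order(data$patient_id, data$time_years), , drop = FALSE]
  ds <- .lme_design_stats(data$patient_id, data$time_years)
  core <- .lme_fit_core(ds, data$value)
  dimnames(core$features) <- list(ds$levels, c("intercept", "slope"))
  structure(c(list(protein = protein, patients = ds$levels), core),
            class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("LME fit%s (%s): beta0 = %.4f, beta1 = %.4f/yr, sigma2 = %.4g\n",
              if (!is.null(x$protein)) paste0(" [", x$protein, "]") else "",
              x$model_form, x$beta[1L], x$beta[2L], x$sigma2))
  cat(sprintf("  random-effect SDs: intercept %.4f, slope %.4f\n",
              sqrt(x$Psi[1, 1]), sqrt(x$Psi[2, 2])))
  invisible(x)
}

#' Per-patient predicted trajectory features from a fitted model
#'
#' Returns the empirical best linear unbiased predictions
#' `(beta0 + u0_i, beta1 + u1_i)` for each patient. Patients contribute
#' shrunken predictions; under an intercept-only model the slope feature
#' equals the fixed slope.
#'
#' @param fit an [fit_lme()] result.
#' @return Matrix with one row per patient and columns `intercept`, `slope`.
#' @export
predict_features <- function(fit) {
  stopifnot(inherits(fit, "lme_fit"))
  fit$features
}

#' Fit trajectory models for every protein of a standardized matrix
#'
#' @param std a `std_matrix` from [log_zscore()].
#' @return A list of class `lme_fits`: per-protein summaries plus the
#'   n_patients x n_proteins matrices of predicted intercepts and slopes.
#' @export
fit_lme_all <- function(std) {
  samp <- std$samples
  ds <- .lme_design_stats(samp$patient_id, samp$time_years)
  prot <- colnames(std$values)
  ints <- slos <- matrix(NA_real_, length(ds$levels), length(prot),
                         dimnames = list(ds$levels, prot))
  info <- data.frame(protein = prot, beta0 = NA_real_, beta1 = NA_real_,
                     sigma2 = NA_real_, psi_int = NA_real_,
                     psi_slo = NA_real_, model_form = NA_character_,
                     converged = NA, stringsAsFactors = FALSE)
  for (j in seq_along(prot)) {
    core <- .lme_fit_core(ds, std$values[, j])
    ints[, j] <- core$features[, 1L]
    slos[, j] <- core$features[, 2L]
    info$beta0[j] <- core$beta[1L]; info$beta1[j] <- core$beta[2L]
    info$sigma2[j] <- core$sigma2
    info$psi_int[j] <- core$Psi[1, 1]; info$psi_slo[j] <- core$Psi[2, 2]
    info$model_form[j] <- core$model_form
    info$converged[j] <- core$converged
  }
  structure(list(intercepts = ints, slopes = slos, info = info,
                 patients = ds$levels),
            class = "lme_fits")
}

#' @export
print.lme_fits <- function(x, ...) {
  cat(sprintf("Trajectory models: %d proteins x %d patients (%d intercept-only, %d degenerate)\n",
              ncol(x$intercepts), nrow(x$intercepts),
              sum(x$info$model_form == "intercept_only"),
              sum(x$info$model_form == "degenerate")))
  invisible(x)
}

#' Assemble the clustering feature matrix
#'
#' In `repeated` mode, binds the per-patient predicted intercepts and slopes
#' into an `n x 2P` matrix and re-standardizes every column to mean 0 and
#' SD 1 so that slope and intercept features contribute comparably to
#' distances. In `single_visit` mode, returns the standardized values at the
#' chosen visit (baseline, second, or last sample per patient); patients
#' without the requested visit are dropped and recorded in the `dropped`
#' attribute.
#'
#' @param x an `lme_fits` object (repeated mode) or a `std_matrix`
#'   (single-visit modes).
#' @param mode one of `"repeated"`, `"baseline"`, `"second"`, `"last"`.
#' @return Feature matrix with patients as rows; attributes `feature_type`
#'   (per column, repeated mode), `mode` and `dropped`.
#' @export
assemble_feature_matrix <- function(x, mode = c("repeated", "baseline",
                                                "second", "last")) {
  mode <- match.arg(mode)
  if (mode == "repeated") {
    stopifnot(inherits(x, "lme_fits"))
    feat <- cbind(x$intercepts, x$slopes)
    colnames(feat) <- c(paste0(colnames(x$intercepts), ":int"),
                        paste0(colnames(x$slopes), ":slo"))
    ctr <- colMeans(feat)
    scl <- apply(feat, 2L, sd)
    scl[scl == 0] <- 1  # constant feature (degenerate protein): leave centred
    feat <- sweep(sweep(feat, 2L, ctr, "-"), 2L, scl, "/")
    attr(feat, "feature_type") <- rep(c("intercept", "slope"),
                                      each = ncol(x$intercepts))
    attr(feat, "mode") <- mode
    attr(feat, "dropped") <- character(0)
    return(feat)
  }
  stopifnot(inherits(x, "std_matrix"))
  samp <- x$samples
  rows <- integer(0); pats <- character(0); dropped <- character(0)
  for (pid in unique(samp$patient_id)) {
    ii <- which(samp$patient_id == pid)
    ii <- ii[order(samp$time_years[ii])]
    pick <- switch(mode,
      baseline = ii[which(samp$time_years[ii] == 0)[1L]],
      second = if (length(ii) >= 2L) ii[2L] else NA_integer_,
      last = ii[length(ii)]
    )
    if (is.na(pick)) dropped <- c(dropped, pid)
    else { rows <- c(rows, pick); pats <- c(pats, pid) }
  }
  feat <- x$values[rows, , drop = FALSE]
  rownames(feat) <- pats
  attr(feat, "feature_type") <- rep("level", ncol(feat))
  attr(feat, "mode") <- mode
  attr(feat, "dropped") <- dropped
  feat
}

#' Write / read a trajectory feature matrix as TSV
#'
#' Uses a two-row header: protein identifier and feature type.
#'
#' @param feat feature matrix from [assemble_feature_matrix()].
#' @param path file path.
#' @export
write_feature_matrix <- function(feat, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("patient_id", colnames(feat)), collapse = "\t"), con,
             sep = "\n")
  writeLines(paste(c("#type", attr(feat, "feature_type")), collapse = "\t"),
             con, sep = "\n")
  lines <- paste(rownames(feat),
                 apply(feat, 1L, function(r)
                   paste(.fmt_num(r), collapse = "\t")), sep = "\t")
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  types <- strsplit(lines[2L], "\t", fixed = TRUE)[[1]][-1L]
  recs <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  pats <- vapply(recs, `[`, "", 1L)
  m <- do.call(rbind, lapply(recs, function(r) as.numeric(r[-1L])))
  dimnames(m) <- list(pats, hdr[-1L])
  attr(m, "feature_type") <- types
  m
}
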