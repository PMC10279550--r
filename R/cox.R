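# Cox proportional hazards with Efron tie handling, maximized by
# Newton-Raphson with step-halving; Harrell's C with bootstrap optimism
# correction; Kaplan-Meier / log-rank via the survival package.

# Efron partial log-likelihood, gradient and Hessian.
.cox_loglik <- function(beta, X, time, status) {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ord <- order(time)
  Xo <- X[ord, , drop = FALSE]; to <- time[ord]
  so <- status[ord]; wo <- w[ord]; eo <- eta[ord]

  ll <- 0
  g <- numeric(p)
  Hm <- matrix(0, p, p)
  ut <- unique(to[so == 1])
  for (tt in ut) {
    at_risk <- which(to >= tt)
    died <- which(to == tt & so == 1)
    d <- length(died)
    R0 <- sum(wo[at_risk])
    R1 <- colSums(Xo[at_risk, , drop = FALSE] * wo[at_risk])
    XR <- Xo[at_risk, , drop = FALSE] * sqrt(wo[at_risk])
    R2 <- crossprod(XR)
    D0 <- sum(wo[died])
    D1 <- colSums(Xo[died, , drop = FALSE] * wo[died])
    XD <- Xo[died, , drop = FALSE] * sqrt(wo[died])
    D2 <- crossprod(XD)

    ll <- ll + sum(eo[died])
    for (l in seq_len(d) - 1L) {
      f <- l / d
      phi0 <- R0 - f * D0
      phi1 <- R1 - f * D1
      phi2 <- R2 - f * D2
      ll <- ll - log(phi0)
      g <- g - phi1 / phi0
      Hm <- Hm - (phi2 / phi0 - tcrossprod(phi1 / phi0))
    }
    g <- g + colSums(Xo[died, , drop = FALSE])
  }
  list(loglik = ll, gradient = g, hessian = Hm)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Efron partial likelihood by Newton-Raphson with
#' step-halving (so the log-likelihood never decreases across accepted
#' steps), stopping when the gradient norm falls below `tol` or after
#' `max_iter` iterations. Reports Wald statistics, hazard ratios with 95%
#' confidence intervals, AIC and BIC (on the number of events).
#'
#' @param X numeric design matrix (no constant columns); column names label
#'   the coefficients.
#' @param time event/censoring times (> 0).
#' @param event logical or 0/1 event indicators (>= 1 event).
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return Object of class `cox_fit`: `coef`, `se`, `hr`, `ci_lower`,
#'   `ci_upper`, `p`, `loglik`, `loglik_null`, `AIC`, `BIC`, `n`,
#'   `n_events`, `iterations`, `converged`.
#' @export
fit_cox <- function(X, time, event, tol = 1e-9, max_iter = 100L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  event <- as.integer(as.logical(event))
  if (sum(event) < 1L) stop("need at least one event", call. = FALSE)
  if (nrow(X) != length(time) || length(time) != length(event))
    stop("X, time and event must align", call. = FALSE)
  cols <- colnames(X) %||% sprintf("x%d", seq_len(ncol(X)))
  colnames(X) <- cols
  const <- apply(X, 2L, function(x) max(x) - min(x)) == 0
  if (any(const))
    stop(sprintf("constant covariate: %s", cols[which(const)[1L]]),
         call. = FALSE)

  p <- ncol(X)
  beta <- numeric(p)
  ev0 <- .cox_loglik(beta, X, time, event)
  loglik_null <- ev0$loglik
  ev <- ev0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (sqrt(sum(ev$gradient^2)) < tol) { converged <- TRUE; break }
    Hm <- -ev$hessian
    ch <- tryCatch(chol(Hm), error = function(e) NULL)
    if (is.null(ch) || any(diag(ch) < 1e-10))
      stop("singular information matrix (collinear covariates?)", call. = FALSE)
    step <- backsolve(ch, forwardsolve(t(ch), ev$gradient))
    # step-halving: the accepted iterate never lowers the partial likelihood
    hfac <- 1
    repeat {
      cand <- beta + hfac * step
      ev_c <- .cox_loglik(cand, X, time, event)
      if (ev_c$loglik >= ev$loglik - 1e-12) break
      hfac <- hfac / 2
      if (hfac < 1e-10)
        stop("step-halving failed to improve the partial likelihood",
             call. = FALSE)
    }
    beta <- beta + hfac * step
    ev <- ev_c
    if (any(abs(beta) > 20)) {
      worst <- cols[which.max(abs(beta))]
      stop(sprintf("monotone likelihood / separation detected for covariate '%s'",
                   worst), call. = FALSE)
    }
  }
  if (!converged && sqrt(sum(ev$gradient^2)) < tol) converged <- TRUE
  Hm <- -ev$hessian
  vcov <- tryCatch(solve(Hm), error = function(e)
    stop("singular information matrix (collinear covariates?)", call. = FALSE))
  se <- sqrt(pmax(diag(vcov), 0))
  z <- beta / se
  n_events <- sum(event)
  structure(list(
    coef = setNames(beta, cols), se = setNames(se, cols),
    hr = setNames(exp(beta), cols),
    ci_lower = setNames(exp(beta - 1.96 * se), cols),
    ci_upper = setNames(exp(beta + 1.96 * se), cols),
    p = setNames(2 * pnorm(-abs(z)), cols),
    loglik = ev$loglik, loglik_null = loglik_null,
    AIC = -2 * ev$loglik + 2 * p,
    BIC = -2 * ev$loglik + p * log(n_events),
    vcov = vcov, n = nrow(X), n_events = n_events,
    iterations = iter, converged = converged,
    X = X, time = time, event = event
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (Efron ties): n = %d, events = %d, loglik = %.3f\n",
              x$n, x$n_events, x$loglik))
  tab <- data.frame(coef = x$coef, HR = x$hr,
                    `95% CI` = sprintf("%.2f-%.2f", x$ci_lower, x$ci_upper),
                    p = signif(x$p, 3), check.names = FALSE)
  print(tab)
  cat(sprintf("AIC = %.1f, BIC = %.1f\n", x$AIC, x$BIC))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs in which the higher-risk subject fails earlier.
#' A pair is usable when the ordering of failure times is determinable under
#' censoring; tied risk scores count 1/2.
#'
#' @param risk numeric risk scores (higher = worse prognosis).
#' @param time event/censoring times.
#' @param event event indicators.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_c <- function(risk, time, event) {
  event <- as.logical(event)
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  Ti <- matrix(time, n, n); Tj <- t(Ti)
  Ei <- matrix(event, n, n); Ej <- t(Ei)
  Ri <- matrix(risk, n, n); Rj <- t(Ri)
  # ordered pairs (i, j) where i is observed to fail before j's exit:
  # either i's event strictly precedes j, or they tie in time and only i
  # had the event (j is then known to survive at least as long)
  usable_ij <- (Ti < Tj & Ei) | (Ti == Tj & Ei & !Ej)
  diag(usable_ij) <- FALSE
  nu <- sum(usable_ij)
  if (nu == 0L) stop("no usable pairs", call. = FALSE)
  conc <- sum(usable_ij & (Ri > Rj)) + 0.5 * sum(usable_ij & (Ri == Rj))
  conc / nu
}

#' Optimism-corrected concordance via Harrell's bootstrap
#'
#' Fits the model on `B` bootstrap samples; each refit's concordance on its
#' own bootstrap sample minus its concordance on the original data estimates
#' the optimism, whose mean is subtracted from the apparent concordance.
#'
#' @param X design matrix.
#' @param time,event outcome.
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @param max_fail_frac error out if more than this fraction of bootstrap
#'   fits fail.
#' @return List with `apparent`, `corrected`, `optimism`, `B_used`.
#' @export
optimism_corrected_c <- function(X, time, event, B = 200L, seed = 1L,
                                 max_fail_frac = 0.1) {
  X <- as.matrix(X)
  fit <- fit_cox(X, time, event)
  apparent <- harrell_c(drop(X %*% fit$coef), time, event)
  n <- nrow(X)
  opt <- numeric(0)
  failures <- 0L
  draws <- with_local_seed(seed, lapply(seq_len(B), function(b)
    sample.int(n, n, replace = TRUE)))
  for (b in seq_len(B)) {
    idx <- draws[[b]]
    Xb <- X[idx, , drop = FALSE]
    # a resample can make a dummy column constant; drop it for this refit
    # (its coefficient is 0 on both the bootstrap and the original data)
    keep <- apply(Xb, 2L, function(x) max(x) - min(x)) > 0
    if (!any(keep)) { failures <- failures + 1L; next }
    fb <- tryCatch(fit_cox(Xb[, keep, drop = FALSE], time[idx], event[idx]),
                   error = function(e) NULL)
    if (is.null(fb)) { failures <- failures + 1L; next }
    c_boot <- tryCatch(
      harrell_c(drop(Xb[, keep, drop = FALSE] %*% fb$coef),
                time[idx], event[idx]),
      error = function(e) NA_real_)
    c_orig <- harrell_c(drop(X[, keep, drop = FALSE] %*% fb$coef), time, event)
    if (is.na(c_boot)) { failures <- failures + 1L; next }
    opt <- c(opt, c_boot - c_orig)
  }
  if (failures > max_fail_frac * B)
    stop(sprintf("%d of %d bootstrap fits failed", failures, B), call. = FALSE)
  list(apparent = apparent, corrected = apparent - mean(opt),
       optimism = mean(opt), B_used = length(opt))
}

#' Kaplan-Meier curves and the K-group log-rank test
#'
#' Product-limit survival estimates per group and the log-rank chi-square
#' with `groups - 1` degrees of freedom (via the survival package).
#'
#' @param time,event outcome.
#' @param groups group labels (>= 2 non-empty groups).
#' @return List with `fit` (a `survfit` object), `chisq`, `df`, `p`.
#' @export
kaplan_meier_logrank <- function(time, event, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("need at least 2 non-empty groups", call. = FALSE)
  if (any(table(groups) == 0L)) stop("empty group", call. = FALSE)
  if (sum(event) < 1L) stop("need at least one event", call. = FALSE)
  event <- as.integer(as.logical(event))
  df_in <- data.frame(time = time, event = event, g = droplevels(groups))
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = df_in)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df_in)
  df <- nlevels(df_in$g) - 1L
  chisq <- unname(sd$chisq)
  list(fit = fit, chisq = chisq, df = df,
       p = pchisq(chisq, df, lower.tail = FALSE))
}
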