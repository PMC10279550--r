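# Independent oracle implementations used to cross-check the package.
# These follow the textbook formulas directly (dense matrices, explicit
# loops) and deliberately share no code with the implementation.

# Generalized-least-squares / Henderson mixed-model-equations oracle for the
# random intercept+slope model at given variance components.
henderson_oracle <- function(patient, time, y, Psi, sigma2) {
  pid <- factor(patient, levels = unique(patient))
  n <- nlevels(pid)
  N <- length(y)
  X <- cbind(1, time)
  Z <- matrix(0, N, 2 * n)
  for (i in seq_len(N)) {
    j <- as.integer(pid[i])
    Z[i, 2 * j - 1] <- 1
    Z[i, 2 * j] <- time[i]
  }
  G <- kronecker(diag(n), Psi)
  V <- Z %*% G %*% t(Z) + sigma2 * diag(N)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  b <- G %*% t(Z) %*% Vi %*% (y - X %*% beta)
  list(beta = drop(beta),
       blup = matrix(drop(b), ncol = 2, byrow = TRUE,
                     dimnames = list(levels(pid), c("b0", "b1"))))
}

# --- brute-force cluster-validity indices (literature formulas, loops) ---

oracle_silhouette <- function(D, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(D[i, labels == cl]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

oracle_ch <- function(X, labels) {
  n <- nrow(X); k <- length(unique(labels))
  grand <- colMeans(X)
  W <- 0; B <- 0
  for (cl in unique(labels)) {
    Xi <- X[labels == cl, , drop = FALSE]
    ci <- colMeans(Xi)
    W <- W + sum(t(t(Xi) - ci)^2)
    B <- B + nrow(Xi) * sum((ci - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

oracle_db <- function(X, labels) {
  cls <- sort(unique(labels)); k <- length(cls)
  ctr <- lapply(cls, function(cl) colMeans(X[labels == cl, , drop = FALSE]))
  sc <- vapply(seq_len(k), function(j) {
    Xi <- X[labels == cls[j], , drop = FALSE]
    mean(sqrt(rowSums(t(t(Xi) - ctr[[j]])^2)))
  }, 0)
  tot <- 0
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      m <- sqrt(sum((ctr[[i]] - ctr[[j]])^2))
      best <- max(best, (sc[i] + sc[j]) / m)
    }
    tot <- tot + best
  }
  tot / k
}

oracle_dunn <- function(D, labels) {
  n <- length(labels)
  min_between <- Inf; max_within <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (labels[i] == labels[j]) max_within <- max(max_within, D[i, j])
    else min_between <- min(min_between, D[i, j])
  }
  min_between / max_within
}

oracle_cindex <- function(D, labels) {
  n <- length(labels)
  dw <- c(); dall <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dall <- c(dall, D[i, j])
    if (labels[i] == labels[j]) dw <- c(dw, D[i, j])
  }
  nw <- length(dw)
  ds <- sort(dall)
  smin <- sum(ds[1:nw]); smax <- sum(rev(ds)[1:nw])
  (sum(dw) - smin) / (smax - smin)
}

oracle_hartigan <- function(wk, wk1, n, k) (wk / wk1 - 1) * (n - k - 1)

# gap formula recomputed from the reference log-W draws
oracle_gap <- function(logW_ref_k, wk) mean(logW_ref_k) - log(wk)
oracle_gap_se <- function(logW_ref_k) {
  B <- length(logW_ref_k)
  sd(logW_ref_k) * sqrt(1 + 1 / B)
}

# --- survival oracles ---

oracle_harrell <- function(risk, time, event) {
  n <- length(risk)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    usable <- (time[i] < time[j] && event[i]) ||
      (time[i] == time[j] && event[i] && !event[j])
    if (!usable) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  num / den
}

# Efron partial log-likelihood by direct summation (for grid-search checks).
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (tt in sort(unique(time[event == 1]))) {
    died <- which(time == tt & event == 1)
    risk <- which(time >= tt)
    d <- length(died)
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum(exp(x[risk] * beta)) -
                       (l / d) * sum(exp(x[died] * beta)))
    }
    ll <- ll + sum(x[died] * beta)
  }
  ll
}

# closed-form balanced random-intercept shrinkage score
oracle_subset_score <- function(X, mu, psi2, sigma2) {
  P <- ncol(X)
  lam <- psi2 / (psi2 + sigma2 / P)
  mu + lam * (rowMeans(X) - mu)
}
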