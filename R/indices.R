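# Cluster-validity index ensemble. Seven indices spanning the
# compactness/separation families; each votes for the k it optimizes and the
# modal vote wins (ties toward smaller k). Hartigan and the gap statistic
# need solutions at k+1, so callers cluster one k beyond the top of k_range.

.index_silhouette <- function(D, labels) {
  n <- length(labels)
  ks <- sort(unique(labels))
  M <- outer(labels, ks, "==") + 0
  Ssum <- D %*% M                        # n x k: summed distance to clusters
  m <- colSums(M)
  own <- match(labels, ks)
  a <- Ssum[cbind(seq_len(n), own)] / pmax(m[own] - 1, 1)
  other <- Ssum / rep(m, each = n)
  other[cbind(seq_len(n), own)] <- Inf
  b <- apply(other, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[m[own] == 1L] <- 0                   # singleton convention
  s[!is.finite(s)] <- 0                  # all-identical convention: 0
  mean(s)
}

.index_ch <- function(X, labels) {
  n <- nrow(X)
  k <- length(unique(labels))
  if (k < 2L || k >= n) return(NA_real_)
  W <- .wss_from_labels(X, labels)
  Tss <- sum(sweep(X, 2L, colMeans(X), "-")^2)
  B <- Tss - W
  if (W <= 0) return(NA_real_)
  (B / (k - 1)) / (W / (n - k))
}

.index_db <- function(X, labels) {
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2L) return(NA_real_)
  ctr <- t(vapply(ks, function(j) colMeans(X[labels == j, , drop = FALSE]),
                  numeric(ncol(X))))
  scat <- vapply(seq_len(k), function(j) {
    Xi <- X[labels == ks[j], , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xi, 2L, ctr[j, ], "-")^2)))
  }, 0)
  Md <- sqrt(.dist2(ctr, ctr))
  if (any(Md[upper.tri(Md)] == 0)) return(NA_real_)  # coincident centroids
  R <- outer(scat, scat, "+") / Md
  diag(R) <- -Inf
  mean(apply(R, 1L, max))
}

.index_dunn <- function(D, labels) {
  ks <- sort(unique(labels))
  if (length(ks) < 2L) return(NA_real_)
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  diam <- max(D[same & !is.na(same)], 0)
  if (diam == 0) return(NA_real_)
  min(D[!same & !is.na(same)]) / diam
}

.index_cindex <- function(D, labels) {
  d <- D[upper.tri(D)]
  within <- (outer(labels, labels, "=="))[upper.tri(D)]
  nw <- sum(within)
  if (nw == 0L || nw == length(d)) return(NA_real_)
  Sw <- sum(d[within])
  ds <- sort(d)
  Smin <- sum(ds[seq_len(nw)])
  Smax <- sum(ds[seq.int(length(ds) - nw + 1L, length(ds))])
  if (Smax == Smin) return(NA_real_)
  (Sw - Smin) / (Smax - Smin)
}

# Gap statistic: B uniform reference sets drawn in the bounding box of X,
# clustered with the same k; gap(k) = mean_b log W*_b - log W(k).
.gap_references <- function(X, B, seed) {
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  with_local_seed(seed, lapply(seq_len(B), function(b) {
    R <- matrix(runif(nrow(X) * ncol(X)), nrow(X), ncol(X))
    sweep(sweep(R, 2L, hi - lo, "*"), 2L, lo, "+")
  }))
}

.gap_stats <- function(X, wss_by_k, ks_all, B = 20L, seed = 1L,
                       ref_n_init = 1L, keep_refs = FALSE) {
  refs <- .gap_references(X, B, seed)
  logW_ref <- matrix(NA_real_, B, length(ks_all),
                     dimnames = list(NULL, ks_all))
  ref_labels <- if (keep_refs) vector("list", B) else NULL
  for (b in seq_len(B)) {
    if (keep_refs) ref_labels[[b]] <- list()
    for (ki in seq_along(ks_all)) {
      k <- ks_all[ki]
      sol <- kmeans_assign(refs[[b]], k,
                           seed = derive_seed(seed, sprintf("gap-%d-%d", b, k)),
                           n_init = ref_n_init)
      logW_ref[b, ki] <- log(max(sol$wss, 1e-300))
      if (keep_refs) ref_labels[[b]][[as.character(k)]] <- unname(sol$labels)
    }
  }
  gap <- colMeans(logW_ref) - log(pmax(wss_by_k, 1e-300))
  se <- apply(logW_ref, 2L, sd) * sqrt(1 + 1 / B)
  out <- list(gap = setNames(gap, ks_all), se = setNames(se, ks_all))
  if (keep_refs) {
    out$refs <- refs
    out$ref_labels <- ref_labels
    out$logW_ref <- logW_ref
  }
  out
}

#' Cluster-validity indices over a range of k
#'
#' Computes seven validity indices for each candidate k: mean silhouette
#' (maximize), Calinski-Harabasz (maximize), Davies-Bouldin (minimize),
#' Dunn (maximize), C-index (minimize), the gap statistic (B uniform
#' bounding-box references, 1-SE rule), and Hartigan's rule (smallest k with
#' `H(k) = (W_k / W_{k+1} - 1)(n - k - 1) <= 10`). Indices undefined for a
#' given partition (e.g. coincident centroids, zero diameter) report `NA` and
#' are excluded from the vote.
#'
#' @param X embedding matrix used for clustering.
#' @param solutions named list of `cluster_solution`s, one per k; ks must be
#'   contiguous and include `max(k_range) + 1` (needed by Hartigan and gap).
#' @param k_range integer vector of candidate ks to score.
#' @param gap_B number of gap-statistic reference sets.
#' @param seed seed for the gap references.
#' @param keep_refs keep the gap reference draws and their clusterings (for
#'   auditing the computation).
#' @return Object of class `validity_indices`: `values` (index x k matrix),
#'   `votes` (per-index winning k), `wss`, and optionally `gap_detail`.
#' @export
validity_indices <- function(X, solutions, k_range = 2:8, gap_B = 20L,
                             seed = 1L, keep_refs = FALSE) {
  X <- as.matrix(X)
  ks_have <- sort(as.integer(names(solutions)))
  k_range <- sort(as.integer(k_range))
  if (any(diff(ks_have) != 1L))
    stop("solutions must cover a contiguous range of k", call. = FALSE)
  if (!all(k_range %in% ks_have) || !(max(k_range) + 1L) %in% ks_have)
    stop("solutions must include every k in k_range plus max(k_range) + 1",
         call. = FALSE)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  wss <- vapply(as.character(ks_have), function(kk)
    solutions[[kk]]$wss, 0)

  vals <- matrix(NA_real_, 7L, length(k_range),
                 dimnames = list(c("silhouette", "calinski_harabasz",
                                   "davies_bouldin", "dunn", "c_index",
                                   "gap", "hartigan"),
                                 k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    lab <- unname(solutions[[as.character(k)]]$labels)
    vals["silhouette", ki] <- .index_silhouette(D, lab)
    vals["calinski_harabasz", ki] <- .index_ch(X, lab)
    vals["davies_bouldin", ki] <- .index_db(X, lab)
    vals["dunn", ki] <- .index_dunn(D, lab)
    vals["c_index", ki] <- .index_cindex(D, lab)
    vals["hartigan", ki] <-
      (wss[as.character(k)] / wss[as.character(k + 1L)] - 1) * (n - k - 1)
  }
  gap_ks <- as.character(ks_have)
  gd <- .gap_stats(X, wss[gap_ks], ks_have, B = gap_B, seed = seed,
                   keep_refs = keep_refs)
  vals["gap", ] <- gd$gap[as.character(k_range)]

  votes <- c(
    silhouette = .vote_max(vals["silhouette", ], k_range),
    calinski_harabasz = .vote_max(vals["calinski_harabasz", ], k_range),
    davies_bouldin = .vote_min(vals["davies_bouldin", ], k_range),
    dunn = .vote_max(vals["dunn", ], k_range),
    c_index = .vote_min(vals["c_index", ], k_range),
    gap = .vote_gap(gd$gap, gd$se, k_range),
    hartigan = .vote_hartigan(vals["hartigan", ], k_range)
  )
  structure(list(values = vals, votes = votes, wss = wss,
                 gap_se = gd$se,
                 gap_detail = if (keep_refs) gd else NULL),
            class = "validity_indices")
}

.vote_max <- function(v, ks) {
  if (all(is.na(v))) return(NA_integer_)
  ks[which.max(replace(v, is.na(v), -Inf))]
}
.vote_min <- function(v, ks) {
  if (all(is.na(v))) return(NA_integer_)
  ks[which.min(replace(v, is.na(v), Inf))]
}
.vote_gap <- function(gap, se, ks) {
  # 1-SE rule: smallest k with gap(k) >= gap(k+1) - se(k+1)
  for (k in ks) {
    g_k <- gap[as.character(k)]
    g_k1 <- gap[as.character(k + 1L)]
    s_k1 <- se[as.character(k + 1L)]
    if (is.na(g_k) || is.na(g_k1)) next
    if (g_k >= g_k1 - s_k1) return(k)
  }
  NA_integer_
}
.vote_hartigan <- function(h, ks) {
  ok <- which(!is.na(h) & h <= 10)
  if (!length(ok)) return(NA_integer_)
  ks[min(ok)]
}

#' Combine index votes into a winning k
#'
#' Each index votes for its optimizing k; the winner is the modal vote, ties
#' broken toward the smaller k. Indices with missing votes are excluded.
#'
#' @param votes integer vector of per-index winning ks (NAs allowed).
#' @return The winning k.
#' @export
vote <- function(votes) {
  votes <- votes[!is.na(votes)]
  if (!length(votes)) stop("all indices failed to vote", call. = FALSE)
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}

#' @export
print.validity_indices <- function(x, ...) {
  cat("Cluster-validity indices (columns = k):\n")
  print(round(x$values, 4))
  cat("votes:", paste(sprintf("%s->%s", names(x$votes), x$votes),
                      collapse = ", "), "\n")
  invisible(x)
}
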