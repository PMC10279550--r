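# k-means with k-means++ initialization and Lloyd iterations. The objective
# is asserted non-increasing across iterations, and labels are canonicalized
# (clusters numbered by decreasing size, ties broken by the smallest
# contained row name) so runs are comparable.

.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i1 <- sample.int(n, 1L)
  centers[1L, ] <- X[i1, ]
  if (k > 1L) {
    d2 <- .dist2(X, centers[1L, , drop = FALSE])[, 1L]
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        ij <- sample.int(n, 1L)
      } else {
        ij <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- X[ij, ]
      d2 <- pmin(d2, .dist2(X, centers[j, , drop = FALSE])[, 1L])
    }
  }
  centers
}

.lloyd <- function(X, centers, max_iter = 100L) {
  k <- nrow(centers)
  n <- nrow(X)
  xsq <- rowSums(X^2)
  dist2_to <- function(C) {
    d2 <- xsq + rep(rowSums(C^2), each = n) - 2 * tcrossprod(X, C)
    d2[d2 < 0] <- 0
    d2
  }
  prev_obj <- Inf
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to(centers)
    labels <- max.col(-d2, ties.method = "first")
    obj <- sum(d2[cbind(seq_len(n), labels)])
    # Lloyd's objective never increases across iterations
    stopifnot(obj <= prev_obj + 1e-8 * (1 + abs(prev_obj)))
    cnt <- tabulate(labels, k)
    if (any(cnt == 0L)) {             # refill empty clusters from farthest point
      for (j in which(cnt == 0L)) {
        far <- which.max(d2[cbind(seq_len(n), labels)])
        labels[far] <- j
      }
      cnt <- tabulate(labels, k)
    }
    new_centers <- rowsum(X, labels, reorder = TRUE) / cnt
    if (max(abs(new_centers - centers)) < 1e-12 && it > 1L) {
      centers <- new_centers
      break
    }
    centers <- new_centers
    prev_obj <- obj
  }
  d2 <- dist2_to(centers)
  labels <- max.col(-d2, ties.method = "first")
  obj <- sum(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centers = centers, obj = obj)
}

.canonicalize_labels <- function(labels, ids) {
  k <- max(labels)
  size <- as.integer(table(factor(labels, levels = seq_len(k))))
  first_id <- vapply(seq_len(k), function(j) {
    m <- ids[labels == j]
    if (length(m)) min(m) else ""
  }, "")
  ord <- order(-size, first_id)
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  list(labels = remap[labels], order = ord)
}

#' Assign observations to k clusters
#'
#' Runs `n_init` k-means++ starts of Lloyd's algorithm and keeps the solution
#' with the smallest within-cluster sum of squares. Cluster labels are
#' canonical: clusters are numbered by decreasing size, ties broken by the
#' smallest contained row identifier.
#'
#' @param X numeric matrix (observations x dimensions); row names are used as
#'   identifiers.
#' @param k number of clusters (`1 <= k <= nrow(X)`).
#' @param seed integer seed.
#' @param n_init number of k-means++ restarts.
#' @param max_iter Lloyd iteration cap per start.
#' @return Object of class `cluster_solution`: `labels` (named integer
#'   vector), `centroids`, `k`, `wss` (total within-cluster SS), `seed`,
#'   `n_init`.
#' @export
kmeans_assign <- function(X, k, seed = 1L, n_init = 25L, max_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k cannot exceed the number of observations", call. = FALSE)
  ids <- rownames(X) %||% sprintf("row%06d", seq_len(n))
  best <- NULL
  with_local_seed(seed, {
    for (s in seq_len(n_init)) {
      res <- .lloyd(X, .kmeanspp_init(X, k), max_iter)
      if (is.null(best) || res$obj < best$obj - 1e-12) best <- res
    }
  })
  can <- .canonicalize_labels(best$labels, ids)
  centroids <- best$centers[can$order, , drop = FALSE]
  rownames(centroids) <- NULL
  structure(list(labels = setNames(can$labels, ids), centroids = centroids,
                 k = as.integer(k), wss = best$obj, seed = as.integer(seed),
                 n_init = as.integer(n_init)),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("k-means solution: k = %d, n = %d, within-SS = %.4g\n",
              x$k, length(x$labels), x$wss))
  cat("  cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

# Within-cluster sum of squares recomputed from labels (used by indices).
.wss_from_labels <- function(X, labels) {
  tot <- 0
  for (j in unique(labels)) {
    Xi <- X[labels == j, , drop = FALSE]
    ctr <- colMeans(Xi)
    tot <- tot + sum(sweep(Xi, 2L, ctr, "-")^2)
  }
  tot
}
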