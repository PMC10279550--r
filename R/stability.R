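# Cluster stability under feature-space noise, scored by Jaccard similarity.

#' Jaccard similarity between two sets
#'
#' `|A intersect B| / |A union B|`; two empty sets have similarity 1.
#'
#' @param a,b vectors interpreted as sets.
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Cluster stability under random feature noise
#'
#' Repeats the embedding + k-means pipeline `R` times on copies of the
#' standardized feature matrix perturbed with i.i.d. Gaussian noise
#' `N(0, tau^2)`, and records, for each original cluster, the maximum Jaccard
#' similarity against any perturbed cluster. The per-cluster mean across
#' repeats is the stability score; clusters with mean Jaccard >= 0.75 are
#' flagged stable. The clustering seed of the original solution is reused in
#' every repeat so that all randomness comes from the injected noise; with
#' `tau = 0` the pipeline therefore reproduces the original labels exactly.
#'
#' @param features feature matrix the solution was derived from.
#' @param solution the original `cluster_solution`.
#' @param config the [embed_config()] used for the original embedding.
#' @param tau noise SD on the standardized feature scale.
#' @param R number of noise repeats.
#' @param seed integer seed for the noise draws.
#' @param stable_threshold mean-Jaccard cutoff for the stable flag.
#' @return Object of class `stability_report`: `mean_jaccard` (per original
#'   cluster), `jaccard` (R x k matrix), `tau`, `R`, `stable`.
#' @export
stability <- function(features, solution, config = embed_config(),
                      tau = 0.1, R = 100L, seed = 1L,
                      stable_threshold = 0.75) {
  if (tau < 0) stop("tau must be nonnegative", call. = FALSE)
  features <- as.matrix(features)
  orig <- solution$labels
  stopifnot(length(orig) == nrow(features))
  k <- solution$k
  ids <- names(orig) %||% as.character(seq_along(orig))
  orig_members <- lapply(seq_len(k), function(j) ids[orig == j])

  J <- matrix(NA_real_, R, k)
  noise_draws <- with_local_seed(seed, {
    lapply(seq_len(R), function(r)
      matrix(rnorm(length(features), 0, tau), nrow(features), ncol(features)))
  })
  for (r in seq_len(R)) {
    Xp <- features + noise_draws[[r]]
    rownames(Xp) <- ids
    emb <- embed(Xp, config)
    sol_r <- kmeans_assign(emb, k, seed = solution$seed,
                           n_init = solution$n_init)
    pert_members <- lapply(seq_len(k), function(j) ids[sol_r$labels == j])
    for (j in seq_len(k)) {
      J[r, j] <- max(vapply(pert_members, jaccard, 0, a = orig_members[[j]]))
    }
  }
  mj <- colMeans(J)
  structure(list(mean_jaccard = mj, jaccard = J, tau = tau, R = as.integer(R),
                 stable = mj >= stable_threshold,
                 stable_threshold = stable_threshold,
                 seed = as.integer(seed)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability under noise (tau = %.3g, R = %d):\n", x$tau, x$R))
  for (j in seq_along(x$mean_jaccard))
    cat(sprintf("  cluster %d: mean Jaccard %.3f%s\n", j, x$mean_jaccard[j],
                if (x$stable[j]) " (stable)" else ""))
  invisible(x)
}
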