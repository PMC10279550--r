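# Bootstrap consensus over the validity-index ensemble to choose k.

#' Choose the number of clusters by bootstrap consensus
#'
#' Draws `B` bootstrap resamples of the patients (with replacement,
#' duplicates kept), re-embeds each resample, clusters it for every k in
#' `k_range` (plus one extra k needed by the Hartigan and gap indices),
#' computes the seven validity indices and records each resample's winning k.
#' The histogram of winning ks over resamples and its mode summarize the
#' consensus. Fully seeded: the same inputs and seed reproduce the result
#' exactly.
#'
#' @param features feature matrix (patients x features).
#' @param config an [embed_config()] applied to every resample.
#' @param k_range candidate ks (default 2..8).
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @param n_init k-means restarts per (resample, k).
#' @param gap_B gap-statistic reference sets per resample.
#' @return Object of class `k_selection`: `k_range`, per-resample `winners`,
#'   `votes` (histogram over `k_range`), `modal_k`, `full_data_indices`
#'   (indices on the unresampled data), and `skipped` (resamples where every
#'   index failed).
#' @export
select_k_bootstrap <- function(features, config = embed_config(),
                               k_range = 2:8, B = 100L, seed = 1L,
                               n_init = 10L, gap_B = 20L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (n < 10L) stop("need at least 10 observations", call. = FALSE)
  k_range <- sort(as.integer(k_range))
  ks_all <- c(k_range, max(k_range) + 1L)

  run_one <- function(X, seed_tag) {
    emb_cfg <- config
    emb_cfg$seed <- derive_seed(seed, paste0(seed_tag, "-embed"))
    emb <- embed(X, emb_cfg)
    sols <- lapply(ks_all, function(k)
      kmeans_assign(emb, k, seed = derive_seed(seed, sprintf("%s-km-%d", seed_tag, k)),
                    n_init = n_init))
    names(sols) <- ks_all
    validity_indices(emb, sols, k_range = k_range, gap_B = gap_B,
                     seed = derive_seed(seed, paste0(seed_tag, "-gap")))
  }

  winners <- integer(0)
  skipped <- integer(0)
  idx_draws <- with_local_seed(seed, {
    lapply(seq_len(B), function(b) sample.int(n, n, replace = TRUE))
  })
  for (b in seq_len(B)) {
    Xb <- features[idx_draws[[b]], , drop = FALSE]
    rownames(Xb) <- sprintf("bs%06d", seq_len(n))  # duplicates kept as rows
    res <- tryCatch(run_one(Xb, sprintf("boot-%d", b)), error = function(e) NULL)
    w <- if (is.null(res)) NA_integer_ else
      tryCatch(vote(res$votes), error = function(e) NA_integer_)
    if (is.na(w)) skipped <- c(skipped, b) else winners <- c(winners, w)
  }
  if (!length(winners))
    stop("every bootstrap resample failed to produce a vote", call. = FALSE)

  hist <- table(factor(winners, levels = k_range))
  modal <- vote(winners)
  full <- run_one(features, "full")
  structure(list(k_range = k_range, winners = winners,
                 votes = setNames(as.integer(hist), k_range),
                 modal_k = modal, full_data_indices = full,
                 skipped = skipped, B = as.integer(B),
                 seed = as.integer(seed)),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("Bootstrap k selection (B = %d, %d skipped): modal k = %d\n",
              x$B, length(x$skipped), x$modal_k))
  cat("  votes: ", paste(sprintf("k=%s:%d", names(x$votes), x$votes),
                         collapse = ", "), "\n")
  invisible(x)
}
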