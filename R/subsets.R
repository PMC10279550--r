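# Protein-subset analysis: cluster proteins (not patients), test per-protein
# association with the subphenotypes, and compute per-patient subset scores.

#' Cluster proteins into subsets on one feature axis
#'
#' Treats proteins as objects and patients as dimensions: the intercept (or
#' slope) block of the feature matrix is transposed and clustered by k-means,
#' with k chosen by a single pass of the seven-index vote (no bootstrap).
#' Subsets are lettered A, B, C, ... by decreasing size (ties broken by the
#' smallest contained protein id).
#'
#' @param features feature matrix from [assemble_feature_matrix()]
#'   (repeated mode), or any patients x proteins matrix when `axis` is
#'   `"level"`.
#' @param axis `"intercept"`, `"slope"`, or `"level"` (single-visit values).
#' @param k_range candidate subset counts.
#' @param seed integer seed.
#' @param n_init k-means restarts.
#' @param gap_B gap-statistic reference sets.
#' @return Object of class `protein_partition`: `assignment` (data frame of
#'   seq_id, subset letter), `k`, `sizes`, `votes`, `axis`, `labels` (named
#'   integer vector).
#' @export
cluster_proteins <- function(features, axis = c("intercept", "slope", "level"),
                             k_range = 2:8, seed = 1L, n_init = 25L,
                             gap_B = 20L) {
  axis <- match.arg(axis)
  ft <- attr(features, "feature_type")
  if (!is.null(ft) && axis %in% ft) {
    block <- features[, ft == axis, drop = FALSE]
  } else if (is.null(ft) || axis == "level") {
    block <- features
  } else {
    stop(sprintf("feature matrix has no '%s' block", axis), call. = FALSE)
  }
  Xp <- t(block)  # proteins as objects
  rownames(Xp) <- sub(":(int|slo)$", "", rownames(Xp))
  if (nrow(Xp) < min(k_range) + 1L)
    stop("fewer proteins than the smallest candidate k", call. = FALSE)

  ks_all <- c(sort(as.integer(k_range)), max(k_range) + 1L)
  ks_all <- ks_all[ks_all <= nrow(Xp)]
  k_range_eff <- ks_all[-length(ks_all)]
  sols <- lapply(ks_all, function(k)
    kmeans_assign(Xp, k, seed = derive_seed(seed, sprintf("prot-km-%d", k)),
                  n_init = n_init))
  names(sols) <- ks_all
  vi <- validity_indices(Xp, sols, k_range = k_range_eff, gap_B = gap_B,
                         seed = derive_seed(seed, "prot-gap"))
  k <- vote(vi$votes)
  sol <- sols[[as.character(k)]]
  letters_k <- make.unique(c(LETTERS, paste0("Z", seq_len(max(0, k - 26)))))[seq_len(k)]
  assignment <- data.frame(seq_id = names(sol$labels),
                           subset = letters_k[sol$labels],
                           stringsAsFactors = FALSE)
  assignment <- assignment[order(assignment$seq_id), , drop = FALSE]
  rownames(assignment) <- NULL
  structure(list(assignment = assignment, k = k,
                 sizes = table(assignment$subset),
                 votes = vi$votes, axis = axis,
                 labels = setNames(sol$labels, names(sol$labels)),
                 indices = vi),
            class = "protein_partition")
}

#' @export
print.protein_partition <- function(x, ...) {
  cat(sprintf("Protein subsets (%s axis): %d subsets over %d proteins\n",
              x$axis, x$k, nrow(x$assignment)))
  print(x$sizes)
  invisible(x)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with tie correction; the p-value comes from the
#' chi-square distribution with `groups - 1` degrees of freedom.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 distinct groups, each non-empty).
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (length(unique(values)) == 1L)  # constant input: no evidence, H = 0
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH q-values (with the usual monotonicity enforcement) and reject
#' flags at the chosen FDR level; the step-up rule rejects where
#' `q_value <= q`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `q_values` and logical `reject`.
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  qv <- p.adjust(p, method = "BH")
  list(q_values = qv, reject = qv <= q)
}

#' Per-protein driver statistics for a subset partition
#'
#' Tests every protein's feature values (on the partition's axis) against the
#' patient subphenotype labels with Kruskal-Wallis, adjusts jointly across
#' all proteins of the axis with Benjamini-Hochberg, and summarizes per
#' subset: the fraction of significant proteins and a ranked top-n driver
#' list (ascending q, then descending H).
#'
#' @param partition a `protein_partition`.
#' @param features the repeated-mode feature matrix (or the matrix used for
#'   the partition).
#' @param patient_labels named subphenotype labels covering the feature rows.
#' @param top_n drivers to list per subset.
#' @param alpha significance level on q-values.
#' @return Object of class `driver_stats`: `table` (per-protein H, df, p, q,
#'   subset, significant), `subset_summary`, `top_drivers`.
#' @export
driver_summary <- function(partition, features, patient_labels, top_n = 10L,
                           alpha = 0.05) {
  ft <- attr(features, "feature_type")
  axis <- partition$axis
  if (!is.null(ft) && axis %in% ft) {
    block <- features[, ft == axis, drop = FALSE]
    colnames(block) <- sub(":(int|slo)$", "", colnames(block))
  } else block <- features
  labs <- patient_labels[rownames(block)]
  prot <- partition$assignment$seq_id
  block <- block[, prot, drop = FALSE]

  H <- p <- numeric(length(prot))
  df <- integer(length(prot))
  for (j in seq_along(prot)) {
    kt <- kruskal_wallis(block[, j], labs)
    H[j] <- kt$H; df[j] <- kt$df; p[j] <- kt$p
  }
  adj <- bh_adjust(p, q = alpha)
  tab <- data.frame(seq_id = prot, subset = partition$assignment$subset,
                    H = H, df = df, p = p, q = adj$q_values,
                    significant = adj$reject, stringsAsFactors = FALSE)
  agg <- split(tab, tab$subset)
  subset_summary <- data.frame(
    subset = names(agg),
    n_proteins = vapply(agg, nrow, 0L),
    n_significant = vapply(agg, function(d) sum(d$significant), 0L),
    fraction_significant = vapply(agg, function(d) mean(d$significant), 0),
    stringsAsFactors = FALSE
  )
  rownames(subset_summary) <- NULL
  top_drivers <- lapply(agg, function(d) {
    d <- d[order(d$q, -d$H), , drop = FALSE]
    head(d, top_n)
  })
  structure(list(table = tab, subset_summary = subset_summary,
                 top_drivers = top_drivers, axis = partition$axis,
                 alpha = alpha),
            class = "driver_stats")
}

#' @export
print.driver_stats <- function(x, ...) {
  cat(sprintf("Driver statistics (%s axis):\n", x$axis))
  print(x$subset_summary, row.names = FALSE)
  invisible(x)
}

#' Per-patient subset score via a random-intercepts model
#'
#' For the proteins of one subset, fits `x_ip = mu + u_i + e_ip` with
#' `u_i ~ N(0, psi2)` and `e_ip ~ N(0, sigma2)` by REML and returns
#' `score_i = mu + BLUP(u_i)` — the shrunken per-patient mean of the subset's
#' feature values. If the between-patient variance estimate is zero, all
#' scores equal `mu` and the result is flagged.
#'
#' @param axis_values patients x proteins matrix of standardized feature
#'   values on the relevant axis.
#' @param subset_proteins character vector of proteins in the subset.
#' @return Named numeric vector of scores with attributes `mu`, `psi2`,
#'   `sigma2`, `degenerate`.
#' @export
subset_patient_score <- function(axis_values, subset_proteins) {
  if (!length(subset_proteins)) stop("subset is empty", call. = FALSE)
  X <- axis_values[, subset_proteins, drop = FALSE]
  n_i <- rep(ncol(X), nrow(X))
  Sy <- rowSums(X)
  Syy <- sum(X^2)
  N <- length(X)

  obj <- function(ltheta) {
    gam <- exp(ltheta)
    w <- 1 / (1 + gam * n_i)
    Fd <- sum(n_i * w)
    gv <- sum(Sy * w)
    mu <- gv / Fd
    yy <- Syy - gam * sum(Sy^2 * w)
    rss <- yy - mu * gv
    if (rss <= 0) return(1e12)
    sigma2 <- rss / (N - 1)
    (N - 1) * log(sigma2) + sum(log(1 + gam * n_i)) + log(Fd)
  }
  op <- optimize(obj, interval = c(-30, 15), tol = 1e-12)
  gam <- exp(op$minimum)
  w <- 1 / (1 + gam * n_i)
  Fd <- sum(n_i * w)
  mu <- sum(Sy * w) / Fd
  yy <- Syy - gam * sum(Sy^2 * w)
  sigma2 <- max(yy - mu * sum(Sy * w), 0) / (N - 1)
  psi2 <- gam * sigma2
  degenerate <- gam < 1e-10
  scores <- if (degenerate) rep(mu, nrow(X)) else
    mu + gam * w * (Sy - n_i * mu)
  structure(setNames(scores, rownames(X)), mu = mu, psi2 = psi2,
            sigma2 = sigma2, degenerate = degenerate)
}
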