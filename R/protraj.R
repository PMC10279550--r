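# Top-level fitting interface: longitudinal protein table -> subphenotypes.

#' Derive proteomic subphenotypes from longitudinal protein measurements
#'
#' The main fitting function. Applies the aptamer filters (when an annotation
#' is given) and the per-patient sample-selection rule, log-transforms and
#' Z-scores the retained measurements, turns them into per-patient trajectory
#' features (predicted intercepts and slopes from per-protein linear mixed
#' models in `repeated` mode, or standardized single-visit values otherwise),
#' embeds the features, selects the number of clusters by bootstrap consensus
#' over seven validity indices, assigns patients by k-means, and scores
#' cluster stability under feature noise.
#'
#' @param long long-format protein table (see [read_long_protein_table()]).
#' @param outcomes outcome table (used for the sample-selection rule).
#' @param annotation optional aptamer annotation; when given, aptamers are
#'   filtered to human, validated, highest-affinity reagents.
#' @param mode `"repeated"` (trajectory features) or a single-visit mode
#'   (`"baseline"`, `"second"`, `"last"`).
#' @param k fixed number of clusters; `NULL` (default) selects k by
#'   bootstrap consensus.
#' @param k_range candidate ks for the consensus.
#' @param B_boot bootstrap resamples for k selection.
#' @param embedding an [embed_config()].
#' @param tau,R_stab noise SD and repeats for the stability analysis.
#' @param n_init k-means restarts for the final assignment.
#' @param boot_n_init k-means restarts inside each bootstrap resample.
#' @param seed master seed; all stage seeds are derived from it.
#' @return An object of class `protraj` with the standardized matrix, the
#'   trajectory models (repeated mode), the feature matrix and embedding, the
#'   k-selection result, the final `cluster_solution` and the stability
#'   report. Supports `print()`, `summary()`, `plot()` and `predict()`.
#' @export
protraj <- function(long, outcomes, annotation = NULL,
                    mode = c("repeated", "baseline", "second", "last"),
                    k = NULL, k_range = 2:8, B_boot = 100L,
                    embedding = embed_config(), tau = 0.1, R_stab = 100L,
                    n_init = 25L, boot_n_init = 10L, seed = 1L) {
  mode <- match.arg(mode)
  cl <- match.call()
  retained <- if (!is.null(annotation)) filter_aptamers(annotation) else NULL
  selected <- select_samples(long, outcomes)
  std <- log_zscore(selected, retained)

  fits <- NULL
  if (mode == "repeated") {
    fits <- fit_lme_all(std)
    features <- assemble_feature_matrix(fits, mode = "repeated")
  } else {
    features <- assemble_feature_matrix(std, mode = mode)
  }

  k_selection <- NULL
  if (is.null(k)) {
    k_selection <- select_k_bootstrap(features, config = embedding,
                                      k_range = k_range, B = B_boot,
                                      seed = derive_seed(seed, "kselect"),
                                      n_init = boot_n_init)
    k <- k_selection$modal_k
  }
  emb_cfg <- embedding
  emb_cfg$seed <- derive_seed(seed, "embed")
  emb <- embed(features, emb_cfg)
  solution <- kmeans_assign(emb, k, seed = derive_seed(seed, "kmeans"),
                            n_init = n_init)
  stab <- stability(features, solution, config = emb_cfg, tau = tau,
                    R = R_stab, seed = derive_seed(seed, "stability"))

  structure(list(call = cl, mode = mode, retained = retained, std = std,
                 fits = fits, features = features, embedding = emb,
                 embed_config = emb_cfg, k_selection = k_selection,
                 solution = solution, stability = stab,
                 seed = as.integer(seed)),
            class = "protraj")
}

#' @export
print.protraj <- function(x, ...) {
  cat(sprintf("Proteomic subphenotypes (%s mode): %d patients, %d proteins, k = %d\n",
              x$mode, nrow(x$features),
              if (x$mode == "repeated") ncol(x$features) / 2 else
                ncol(x$features),
              x$solution$k))
  cat("  cluster sizes:", paste(table(x$solution$labels), collapse = ", "),
      "\n")
  if (!is.null(x$k_selection))
    cat(sprintf("  modal k over %d bootstrap resamples: %d\n",
                x$k_selection$B, x$k_selection$modal_k))
  cat(sprintf("  stability (tau = %.2g): mean Jaccard %s\n", x$stability$tau,
              paste(sprintf("%.2f", x$stability$mean_jaccard), collapse = ", ")))
  invisible(x)
}

#' @export
summary.protraj <- function(object, ...) {
  out <- list(mode = object$mode,
              n_patients = nrow(object$features),
              k = object$solution$k,
              sizes = table(object$solution$labels),
              votes = object$k_selection$votes,
              mean_jaccard = object$stability$mean_jaccard,
              stable = object$stability$stable,
              wss = object$solution$wss)
  class(out) <- "summary.protraj"
  out
}

#' @export
print.summary.protraj <- function(x, ...) {
  cat(sprintf("Subphenotype model (%s mode), %d patients, k = %d\n",
              x$mode, x$n_patients, x$k))
  cat("cluster sizes:\n"); print(x$sizes)
  if (!is.null(x$votes)) { cat("bootstrap k votes:\n"); print(x$votes) }
  cat("stability (mean Jaccard per cluster):\n")
  print(round(x$mean_jaccard, 3))
  invisible(x)
}

#' @export
plot.protraj <- function(x, ...) {
  emb <- x$embedding
  graphics::plot(emb[, 1L], emb[, 2L], col = x$solution$labels,
                 pch = 19, cex = 0.7,
                 xlab = "component 1", ylab = "component 2",
                 main = sprintf("Subphenotypes (k = %d, %s mode)",
                                x$solution$k, x$mode), ...)
  graphics::points(x$solution$centroids[, 1L], x$solution$centroids[, 2L],
                   pch = 3, cex = 2, lwd = 2)
  invisible(x)
}

#' Assign new observations to the fitted subphenotypes
#'
#' Projects new feature rows through the stored embedding (exact for PCA and
#' identity embeddings) and assigns each to the nearest cluster centroid.
#'
#' @param object a fitted `protraj` model.
#' @param newdata feature matrix with the same columns as the training
#'   features.
#' @param ... unused.
#' @return Named integer vector of cluster assignments.
#' @export
predict.protraj <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$features))
    stop("newdata must have the same feature columns as the fit", call. = FALSE)
  emb_new <- switch(object$embed_config$method,
    none = newdata,
    pca = {
      rot <- attr(object$embedding, "rotation")
      ctr <- attr(object$embedding, "center")
      sweep(newdata, 2L, ctr, "-") %*% rot
    },
    umap = stop("prediction is not available for UMAP embeddings",
                call. = FALSE)
  )
  d2 <- .dist2(emb_new, object$solution$centroids)
  lab <- max.col(-d2, ties.method = "first")
  setNames(as.integer(lab), rownames(newdata))
}

#' Cluster labels of a fitted subphenotype model
#'
#' @param fit a `protraj` object.
#' @return Named integer vector of subphenotype labels.
#' @export
cluster_labels <- function(fit) {
  stopifnot(inherits(fit, "protraj"))
  fit$solution$labels
}
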