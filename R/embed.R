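# Dimensionality reduction in front of patient clustering.

#' Embedding configuration
#'
#' @param method `"pca"` (principal-component scores; the deterministic
#'   default), `"umap"` (uniform manifold approximation, library-backed by
#'   the Python `umap-learn` package), or `"none"` (identity).
#' @param n_components number of output dimensions (>= 2).
#' @param n_neighbors UMAP neighborhood size.
#' @param min_dist UMAP minimum embedding distance, in `[0, 1)`.
#' @param seed integer seed (UMAP `random_state`).
#' @return Object of class `embed_config`.
#' @export
embed_config <- function(method = c("pca", "umap", "none"), n_components = 2L,
                         n_neighbors = 15L, min_dist = 0.1, seed = 1L) {
  method <- match.arg(method)
  n_components <- as.integer(n_components)
  if (n_components < 2L) stop("n_components must be >= 2", call. = FALSE)
  if (min_dist < 0 || min_dist >= 1)
    stop("min_dist must be in [0, 1)", call. = FALSE)
  structure(list(method = method, n_components = n_components,
                 n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
                 seed = as.integer(seed)),
            class = "embed_config")
}

# PCA scores via the thinner side of the eigendecomposition; component signs
# are fixed (largest-magnitude loading positive) for run-to-run comparability.
.pca_scores <- function(X, nc) {
  Xc <- sweep(X, 2L, colMeans(X), "-")
  n <- nrow(Xc); d <- ncol(Xc)
  if (nc > min(n - 1L, d))
    stop("n_components exceeds the rank bound of the data", call. = FALSE)
  if (d <= n) {
    e <- eigen(crossprod(Xc) / (n - 1L), symmetric = TRUE)
    rot <- e$vectors[, seq_len(nc), drop = FALSE]
    sgn <- vapply(seq_len(nc), function(j) {
      v <- rot[, j]; if (v[which.max(abs(v))] < 0) -1 else 1
    }, 0)
    rot <- sweep(rot, 2L, sgn, "*")
    scores <- Xc %*% rot
    attr(scores, "rotation") <- rot
  } else {
    e <- eigen(tcrossprod(Xc), symmetric = TRUE)
    U <- e$vectors[, seq_len(nc), drop = FALSE]
    lam <- sqrt(pmax(e$values[seq_len(nc)], 0))
    scores <- sweep(U, 2L, lam, "*")
    rot <- crossprod(Xc, U)
    rot <- sweep(rot, 2L, pmax(lam, 1e-300), "/")
    sgn <- vapply(seq_len(nc), function(j) {
      v <- rot[, j]; if (v[which.max(abs(v))] < 0) -1 else 1
    }, 0)
    scores <- sweep(scores, 2L, sgn, "*")
    rot <- sweep(rot, 2L, sgn, "*")
    attr(scores, "rotation") <- rot
  }
  attr(scores, "center") <- colMeans(X)
  scores
}

.umap_available <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    py <- Sys.which("python")
    ok <- nzchar(py) &&
      system2(py, c("-c", shQuote("import umap")), stdout = FALSE,
              stderr = FALSE) == 0L
    cached <<- ok
    ok
  }
})

.umap_embed <- function(X, cfg) {
  if (!.umap_available())
    stop("UMAP embedding requires a 'python' executable with the umap-learn package on the PATH; use method = 'pca' otherwise",
         call. = FALSE)
  fin <- tempfile(fileext = ".tsv"); fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fin, fout)))
  utils::write.table(X, fin, sep = "\t", row.names = FALSE, col.names = FALSE)
  script <- paste(
    "import sys, numpy as np, umap",
    "X = np.loadtxt(sys.argv[1])",
    "m = umap.UMAP(n_components=int(sys.argv[3]), n_neighbors=int(sys.argv[4]),",
    "              min_dist=float(sys.argv[5]), random_state=int(sys.argv[6]),",
    "              n_jobs=1)",
    "np.savetxt(sys.argv[2], m.fit_transform(X), fmt='%.10g', delimiter='\\t')",
    sep = "\n")
  status <- system2(Sys.which("python"),
                    c("-c", shQuote(script), shQuote(fin), shQuote(fout),
                      cfg$n_components, cfg$n_neighbors, cfg$min_dist,
                      cfg$seed),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("UMAP subprocess failed", call. = FALSE)
  as.matrix(utils::read.table(fout, sep = "\t"))
}

#' Embed a feature matrix for clustering
#'
#' Reduces the feature matrix to `n_components` dimensions. `method = "none"`
#' returns the input unchanged; `"pca"` returns principal-component scores
#' (exact and deterministic); `"umap"` calls the Python `umap-learn`
#' implementation with a fixed `random_state`, making repeated calls with the
#' same seed identical.
#'
#' @param X numeric matrix (observations x features), no missing values.
#' @param config an [embed_config()].
#' @return Embedding matrix (n x n_components; n x d for `"none"`), rows
#'   named as in `X`.
#' @export
embed <- function(X, config = embed_config()) {
  stopifnot(inherits(config, "embed_config"))
  X <- as.matrix(X)
  if (anyNA(X)) stop("feature matrix contains missing values", call. = FALSE)
  if (nrow(X) < config$n_components + 1L)
    stop("need at least n_components + 1 observations", call. = FALSE)
  out <- switch(config$method,
    none = X,
    pca = .pca_scores(X, config$n_components),
    umap = {
      if (config$n_neighbors >= nrow(X))
        stop("n_neighbors must be smaller than the number of observations",
             call. = FALSE)
      .umap_embed(X, config)
    }
  )
  rownames(out) <- rownames(X)
  out
}
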