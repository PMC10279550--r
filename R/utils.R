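#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rexp rbinom runif sd var median quantile setNames
#'   kruskal.test chisq.test fisher.test p.adjust pchisq pnorm qnorm optim
#'   optimize prcomp dist rmultinom
#' @importFrom utils read.table write.table head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# 32-bit-safe polynomial string hash (used only to derive per-stage seeds).
.hash_string <- function(x) {
  codes <- utf8ToInt(x)
  h <- 5381
  for (ch in codes) h <- (h * 33 + ch) %% 2147483629
  h
}

#' Derive a per-stage random seed from a master seed
#'
#' Each stochastic stage of the pipeline receives its own seed, derived
#' deterministically from the master seed and the stage name so that no two
#' stages reuse the same random stream.
#'
#' @param master_seed integer master seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31 - 19)`.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  as.integer((abs(as.numeric(master_seed)) %% 2147483629 +
                .hash_string(stage)) %% 2147483629)
}

# Evaluate expr with a local RNG state; restores the caller's stream.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Squared Euclidean cross-distances between rows of X (n x d) and C (k x d).
.dist2 <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  d2[d2 < 0] <- 0
  d2
}

.assert_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (strict && x <= min)
    stop(sprintf("'%s' must be > %g", name, min), call. = FALSE)
  if (!strict && x < min)
    stop(sprintf("'%s' must be >= %g", name, min), call. = FALSE)
  invisible(x)
}
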