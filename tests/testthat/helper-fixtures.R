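# Programmatic fixtures shared across tests.

make_blobs <- function(centers, n_per = 10L, sd = 1, seed = 1L) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j) {
    matrix(rnorm(n_per * ncol(centers), 0, sd), n_per) +
      matrix(centers[j, ], n_per, ncol(centers), byrow = TRUE)
  }))
  rownames(X) <- sprintf("p%03d", seq_len(nrow(X)))
  attr(X, "truth") <- rep(seq_len(nrow(centers)), each = n_per)
  X
}

six_aptamer_annotation <- function() {
  data.frame(
    seq_id = c("A1", "A2", "A3", "A4", "A5", "A6"),
    target_id = c("P1", "P1", "P2", "P3", "P4", "P5"),
    is_human = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    is_validated = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    affinity_kd = c(1, 5, 1, 1, 2, 9),
    stringsAsFactors = FALSE
  )
}

# a tiny, fully explicit long table: 2 patients x 2 proteins x 2 visits
tiny_long <- function() {
  data.frame(
    patient_id = rep(c("P1", "P2"), each = 4),
    sample_id = rep(c("P1-V1", "P1-V2", "P2-V1", "P2-V2"), each = 2),
    time_years = rep(c(0, 0, 0.5, 0.5, 0, 0, 0.6, 0.6)),
    seq_id = rep(c("SL1", "SL2"), times = 4),
    rfu = c(100, 200, 110, 190, 95, 210, 105, 205),
    stringsAsFactors = FALSE
  )
}

small_cohort <- function(n = 60L, P = 20L, k = 2L, seed = 5L, ...) {
  cohort_config(n_patients = n, n_proteins = P, k_true = k,
                mixing = rep(1 / k, k), n_subsets = min(k, 4L),
                log_hr = c(0, rep(log(2), k - 1L)), seed = seed, ...)
}
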