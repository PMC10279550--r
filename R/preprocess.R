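# Aptamer filtering, sample selection, and standardization.

#' Filter aptamers to human, validated, highest-affinity reagents
#'
#' Removes aptamers with non-human or non-validated targets; when several
#' surviving aptamers target the same protein, only the one with the highest
#' binding affinity (smallest dissociation constant Kd) is kept. Kd ties are
#' broken toward the lexicographically smallest `seq_id` and recorded as a
#' warning.
#'
#' @param annotation aptamer annotation data frame (see
#'   [read_annotation_table()]).
#' @return Character vector of retained `seq_id`s (sorted), with a
#'   `tie_warnings` attribute listing any affinity ties. Idempotent.
#' @export
filter_aptamers <- function(annotation) {
  if (is.null(annotation) || nrow(annotation) == 0L)
    stop("annotation must be non-empty", call. = FALSE)
  ann <- annotation[annotation$is_human & annotation$is_validated, , drop = FALSE]
  ties <- character(0)
  keep <- character(0)
  for (tgt in unique(ann$target_id)) {
    sub <- ann[ann$target_id == tgt, , drop = FALSE]
    best <- sub[sub$affinity_kd == min(sub$affinity_kd), , drop = FALSE]
    if (nrow(best) > 1L) {
      chosen <- min(best$seq_id)
      ties <- c(ties, sprintf(
        "target %s: affinity tie among {%s}; kept %s", tgt,
        paste(sort(best$seq_id), collapse = ", "), chosen))
      warning(sprintf("affinity tie for target %s; keeping %s", tgt, chosen),
              call. = FALSE)
      keep <- c(keep, chosen)
    } else {
      keep <- c(keep, best$seq_id)
    }
  }
  structure(sort(keep), tie_warnings = ties)
}

#' Select the analysis samples per patient
#'
#' Keeps, for every patient, the baseline sample plus the last two samples
#' drawn at or before the outcome time (event or censoring). Depending on how
#' many visits a patient has, this yields one, two or three samples.
#'
#' @param long long protein table.
#' @param outcomes outcome table covering every patient in `long`.
#' @return The filtered long table (same columns, normalized order).
#' @export
select_samples <- function(long, outcomes) {
  miss <- setdiff(unique(long$patient_id), outcomes$patient_id)
  if (length(miss))
    stop(sprintf("patients missing from outcome table: %s",
                 paste(head(miss, 3L), collapse = ", ")), call. = FALSE)
  t_out <- setNames(outcomes$time_to_event_years, outcomes$patient_id)

  # unique (patient, sample, time) visits, via the sample key
  key_all <- paste(long$patient_id, long$sample_id, sep = "\r")
  first <- !duplicated(key_all)
  vis <- data.frame(patient_id = long$patient_id[first],
                    sample_id = long$sample_id[first],
                    time_years = long$time_years[first],
                    key = key_all[first], stringsAsFactors = FALSE)
  keep_key <- character(0)
  for (v in split(vis, vis$patient_id)) {
    pid <- v$patient_id[1L]
    elig <- v[v$time_years <= t_out[[pid]], , drop = FALSE]
    last2 <- elig$key[order(-elig$time_years)][seq_len(min(2L, nrow(elig)))]
    base <- v$key[v$time_years == 0]
    keep_key <- c(keep_key, union(base, last2))
  }
  out <- long[key_all %in% keep_key, , drop = FALSE]
  out <- out[order(out$patient_id, out$time_years, out$seq_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Log-transform and standardize protein measurements to Z-scores
#'
#' Natural-log-transforms RFU values and standardizes each retained protein
#' to mean 0 and sample SD 1 (n-1 denominator) across all retained samples.
#' Zero-variance proteins are dropped and recorded. The standardization
#' constants are stored so the transform can be inverted exactly.
#'
#' @param long long protein table (typically after [select_samples()]).
#' @param retained character vector of `seq_id`s to standardize (e.g. from
#'   [filter_aptamers()]); defaults to all proteins present.
#' @return An object of class `std_matrix`: a list with `values` (samples x
#'   proteins matrix of Z-scores), `samples` (data frame of sample keys),
#'   `center`/`scale` (per-protein log-mean and log-SD), and `dropped`.
#' @export
log_zscore <- function(long, retained = NULL) {
  if (is.null(retained)) retained <- sort(unique(long$seq_id))
  long <- long[long$seq_id %in% retained, , drop = FALSE]
  if (any(long$rfu <= 0)) stop("all RFU values must be positive", call. = FALSE)

  samples <- unique(long[, c("patient_id", "sample_id", "time_years")])
  samples <- samples[order(samples$patient_id, samples$time_years), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  skey <- paste(samples$patient_id, samples$sample_id)
  prot <- sort(unique(long$seq_id))
  i <- match(paste(long$patient_id, long$sample_id), skey)
  j <- match(long$seq_id, prot)
  m <- matrix(NA_real_, nrow(samples), length(prot),
              dimnames = list(samples$sample_id, prot))
  m[cbind(i, j)] <- log(long$rfu)
  if (anyNA(m))
    stop("incomplete sample x protein grid: every retained sample needs a value for every retained protein",
         call. = FALSE)

  center <- colMeans(m)
  scale <- apply(m, 2L, sd)
  dropped <- prot[scale == 0 | !is.finite(scale)]
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance protein(s): %s",
                    length(dropped), paste(head(dropped, 3L), collapse = ", ")),
            call. = FALSE)
    keep <- setdiff(prot, dropped)
    m <- m[, keep, drop = FALSE]
    center <- center[keep]
    scale <- scale[keep]
  }
  z <- sweep(sweep(m, 2L, center, "-"), 2L, scale, "/")
  structure(list(values = z, samples = samples, center = center,
                 scale = scale, dropped = dropped),
            class = "std_matrix")
}

#' Invert a standardized matrix back to log-RFU values
#'
#' @param std a `std_matrix` from [log_zscore()].
#' @return Matrix of natural-log RFU values.
#' @export
unstandardize <- function(std) {
  sweep(sweep(std$values, 2L, std$scale, "*"), 2L, std$center, "+")
}

#' @export
print.std_matrix <- function(x, ...) {
  cat(sprintf("Standardized sample matrix: %d samples x %d proteins (%d dropped)\n",
              nrow(x$values), ncol(x$values), length(x$dropped)))
  invisible(x)
}
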