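# Table readers/writers. All output is tab-separated UTF-8 with LF endings and
# '.' decimals; numeric fields are written with 17 significant digits so that
# write -> read round-trips reproduce doubles exactly.

.num_re <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"

.parse_numeric_col <- function(x, col, file) {
  bad <- !grepl(.num_re, x)
  if (any(bad))
    stop(sprintf("%s: column '%s' has a non-numeric value at data row %d (%s)",
                 file, col, which(bad)[1L], x[which(bad)[1L]]), call. = FALSE)
  as.numeric(x)
}

.read_delim_raw <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  df
}

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L)) & !vapply(df, is.integer, logical(1L))
  out <- df
  for (j in which(num)) out[[j]] <- .fmt_num(df[[j]])
  con <- file(path, open = "wb")  # binary: force LF on every platform
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out) > 0L) {
    lines <- do.call(paste, c(unname(as.list(out)), list(sep = "\t")))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Validate a long-format protein table
#'
#' Checks the contract of the long table: required columns, positive RFU,
#' unique (patient, sample, aptamer) keys, and a baseline (time 0) sample for
#' every patient.
#'
#' @param df data frame with columns `patient_id`, `sample_id`, `time_years`,
#'   `seq_id`, `rfu`.
#' @param file label used in error messages.
#' @return `df`, ordered by (patient, time, aptamer), invisibly valid.
#' @export
validate_long_protein_table <- function(df, file = "long protein table") {
  req <- c("patient_id", "sample_id", "time_years", "seq_id", "rfu")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", file,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (any(is.na(df$time_years)) || any(df$time_years < 0))
    stop(sprintf("%s: negative or missing time_years at row %d", file,
                 which(is.na(df$time_years) | df$time_years < 0)[1L]),
         call. = FALSE)
  bad <- is.na(df$rfu) | df$rfu <= 0
  if (any(bad))
    stop(sprintf("%s: non-positive RFU at row %d", file, which(bad)[1L]),
         call. = FALSE)
  key <- paste(df$patient_id, df$sample_id, df$seq_id, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("%s: duplicate (patient, sample, aptamer) key at row %d",
                 file, anyDuplicated(key)), call. = FALSE)
  has_baseline <- tapply(df$time_years, df$patient_id, function(t) any(t == 0))
  if (!all(has_baseline))
    stop(sprintf("%s: patient '%s' has no baseline (time 0) sample", file,
                 names(has_baseline)[which(!has_baseline)[1L]]), call. = FALSE)
  df <- df[order(df$patient_id, df$time_years, df$seq_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a long-format protein measurement table
#'
#' Expects a delimited text file (TSV, or CSV when the filename ends in
#' `.csv`) with header columns `patient_id`, `sample_id`, `time_years`,
#' `seq_id`, `rfu`. Decimal points only; comma decimals are rejected.
#'
#' @param path file path.
#' @return A validated long protein table ordered by (patient, time, aptamer).
#' @export
read_long_protein_table <- function(path) {
  df <- .read_delim_raw(path)
  req <- c("patient_id", "sample_id", "time_years", "seq_id", "rfu")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df$time_years <- .parse_numeric_col(df$time_years, "time_years", path)
  df$rfu <- .parse_numeric_col(df$rfu, "rfu", path)
  validate_long_protein_table(df[req], file = path)
}

#' @rdname read_long_protein_table
#' @param df a long protein table.
#' @export
write_long_protein_table <- function(df, path) {
  df <- validate_long_protein_table(df)
  .write_tsv(df, path)
}

#' Read/write an aptamer annotation table
#'
#' Columns: `seq_id` (unique), `target_id`, `is_human`, `is_validated`
#' (logical or 0/1), `affinity_kd` (positive dissociation constant; lower
#' means higher binding affinity).
#'
#' @param path file path.
#' @return Annotation data frame.
#' @export
read_annotation_table <- function(path) {
  df <- .read_delim_raw(path)
  req <- c("seq_id", "target_id", "is_human", "is_validated", "affinity_kd")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df$affinity_kd <- .parse_numeric_col(df$affinity_kd, "affinity_kd", path)
  df$is_human <- .parse_logical_col(df$is_human, "is_human", path)
  df$is_validated <- .parse_logical_col(df$is_validated, "is_validated", path)
  if (anyDuplicated(df$seq_id))
    stop(sprintf("%s: duplicate seq_id at row %d", path,
                 anyDuplicated(df$seq_id)), call. = FALSE)
  if (any(df$affinity_kd <= 0))
    stop(sprintf("%s: non-positive affinity_kd at row %d", path,
                 which(df$affinity_kd <= 0)[1L]), call. = FALSE)
  df[req]
}

.parse_logical_col <- function(x, col, file) {
  up <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1")] <- TRUE
  out[up %in% c("FALSE", "F", "0")] <- FALSE
  if (any(is.na(out)))
    stop(sprintf("%s: column '%s' has a non-logical value at data row %d",
                 file, col, which(is.na(out))[1L]), call. = FALSE)
  out
}

#' @rdname read_annotation_table
#' @param df annotation data frame.
#' @export
write_annotation_table <- function(df, path) .write_tsv(df, path)

#' Read/write a clinical covariate table
#'
#' One row per patient. Variable types (numeric / binary / categorical) are
#' carried in a `# types:` comment line so that downstream tests pick the
#' right statistic for each variable.
#'
#' @param path file path.
#' @return Data frame with a `types` attribute (named character vector).
#' @export
read_clinical_table <- function(path) {
  first <- readLines(path, n = 1L)
  types <- NULL
  if (startsWith(first, "# types:")) {
    spec <- trimws(sub("^# types:", "", first))
    parts <- strsplit(strsplit(spec, ",")[[1]], "=")
    types <- setNames(vapply(parts, `[`, "", 2L),
                      vapply(parts, `[`, "", 1L))
  }
  df <- .read_delim_raw(path)
  if (!"patient_id" %in% names(df))
    stop(sprintf("%s: missing 'patient_id' column", path), call. = FALSE)
  if (anyDuplicated(df$patient_id))
    stop(sprintf("%s: duplicate patient_id at row %d", path,
                 anyDuplicated(df$patient_id)), call. = FALSE)
  if (is.null(types)) {  # infer: all-numeric columns are numeric, 0/1 binary
    vars <- setdiff(names(df), "patient_id")
    types <- setNames(rep("categorical", length(vars)), vars)
    for (v in vars) {
      if (all(grepl(.num_re, df[[v]]))) {
        types[[v]] <- if (all(df[[v]] %in% c("0", "1"))) "binary" else "numeric"
      }
    }
  }
  for (v in names(types)) {
    if (!v %in% names(df)) next
    if (types[[v]] %in% c("numeric", "binary"))
      df[[v]] <- .parse_numeric_col(df[[v]], v, path)
    if (types[[v]] == "binary") df[[v]] <- as.integer(df[[v]])
  }
  attr(df, "types") <- types
  df
}

#' @rdname read_clinical_table
#' @param df clinical data frame with a `types` attribute.
#' @export
write_clinical_table <- function(df, path) {
  types <- attr(df, "types")
  con <- file(path, open = "wb")
  if (!is.null(types)) {
    writeLines(paste0("# types: ",
                      paste(sprintf("%s=%s", names(types), types),
                            collapse = ",")), con, sep = "\n")
  }
  close(con)
  tmp <- tempfile()
  .write_tsv(df, tmp)
  body <- readLines(tmp, warn = FALSE)
  unlink(tmp)
  con <- file(path, open = if (is.null(types)) "wb" else "ab")
  writeLines(body, con, sep = "\n")
  close(con)
  invisible(path)
}

#' Read/write a survival outcome table
#'
#' Columns: `patient_id` (unique), `time_to_event_years` (> 0), `event`
#' (0/1 or logical; whether the primary endpoint occurred).
#'
#' @param path file path.
#' @return Outcome data frame with logical `event`.
#' @export
read_outcome_table <- function(path) {
  df <- .read_delim_raw(path)
  req <- c("patient_id", "time_to_event_years", "event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df$time_to_event_years <- .parse_numeric_col(df$time_to_event_years,
                                               "time_to_event_years", path)
  df$event <- .parse_logical_col(df$event, "event", path)
  if (anyDuplicated(df$patient_id))
    stop(sprintf("%s: duplicate patient_id at row %d", path,
                 anyDuplicated(df$patient_id)), call. = FALSE)
  if (any(df$time_to_event_years <= 0))
    stop(sprintf("%s: non-positive time_to_event_years at row %d", path,
                 which(df$time_to_event_years <= 0)[1L]), call. = FALSE)
  df[req]
}

#' @rdname read_outcome_table
#' @param df outcome data frame.
#' @export
write_outcome_table <- function(df, path) .write_tsv(df, path)

#' Read a minimal SomaLogic-style ADAT file
#'
#' Supports a small, read-only dialect of the tab-delimited ADAT layout:
#' `^HEADER` (key/value lines), `^COL_DATA` (aptamer metadata rows, first
#' field is the metadata name; a `SeqId` row is required), `^ROW_DATA`
#' (a `!Fields` line naming the per-sample metadata columns, which must
#' include `PatientId`, `SampleId` and `TimeYears`), and `^TABLE_BEGIN`
#' followed by one data row per sample (row metadata columns then one RFU
#' value per SeqId).
#'
#' @param path file path.
#' @return A list with `long` (long protein table) and `annotation`.
#' @export
read_adat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sent <- function(tag) {
    i <- which(lines == tag)
    if (length(i) != 1L)
      stop(sprintf("%s: missing or duplicated section sentinel %s", path, tag),
           call. = FALSE)
    i
  }
  i_h <- sent("^HEADER"); i_c <- sent("^COL_DATA")
  i_r <- sent("^ROW_DATA"); i_t <- sent("^TABLE_BEGIN")
  if (!(i_h < i_c && i_c < i_r && i_r < i_t))
    stop(sprintf("%s: ADAT sections out of order", path), call. = FALSE)

  split_tab <- function(l) strsplit(l, "\t", fixed = TRUE)[[1]]
  col_lines <- lines[(i_c + 1L):(i_r - 1L)]
  col_meta <- list()
  for (l in col_lines[nzchar(col_lines)]) {
    f <- split_tab(l)
    col_meta[[f[1L]]] <- f[-1L]
  }
  if (is.null(col_meta$SeqId))
    stop(sprintf("%s: column metadata lacks a SeqId row", path), call. = FALSE)
  seq_ids <- col_meta$SeqId
  p <- length(seq_ids)

  row_lines <- lines[(i_r + 1L):(i_t - 1L)]
  fields_line <- row_lines[startsWith(row_lines, "!Fields")]
  if (length(fields_line) != 1L)
    stop(sprintf("%s: ^ROW_DATA must contain exactly one !Fields line", path),
         call. = FALSE)
  fields <- split_tab(fields_line)[-1L]
  need <- c("PatientId", "SampleId", "TimeYears")
  if (!all(need %in% fields))
    stop(sprintf("%s: row metadata fields must include %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)

  data_lines <- lines[(i_t + 1L):length(lines)]
  data_lines <- data_lines[nzchar(data_lines)]
  nmeta <- length(fields)
  recs <- lapply(data_lines, split_tab)
  lens <- lengths(recs)
  if (any(lens != nmeta + p))
    stop(sprintf("%s: ragged data matrix at data row %d (expected %d fields, got %d)",
                 path, which(lens != nmeta + p)[1L], nmeta + p,
                 lens[which(lens != nmeta + p)[1L]]), call. = FALSE)
  meta <- do.call(rbind, lapply(recs, function(r) r[seq_len(nmeta)]))
  colnames(meta) <- fields
  rfu_mat <- do.call(rbind, lapply(recs, function(r)
    .parse_numeric_col(r[-seq_len(nmeta)], "RFU", path)))

  ns <- nrow(rfu_mat)
  long <- data.frame(
    patient_id = rep(meta[, "PatientId"], times = p),
    sample_id = rep(meta[, "SampleId"], times = p),
    time_years = rep(.parse_numeric_col(meta[, "TimeYears"], "TimeYears", path),
                     times = p),
    seq_id = rep(seq_ids, each = ns),
    rfu = as.vector(rfu_mat),
    stringsAsFactors = FALSE
  )
  long <- validate_long_protein_table(long, file = path)

  annotation <- data.frame(
    seq_id = seq_ids,
    target_id = col_meta$Target %||% seq_ids,
    is_human = if (!is.null(col_meta$IsHuman))
      .parse_logical_col(col_meta$IsHuman, "IsHuman", path) else rep(TRUE, p),
    is_validated = if (!is.null(col_meta$IsValidated))
      .parse_logical_col(col_meta$IsValidated, "IsValidated", path)
      else rep(TRUE, p),
    affinity_kd = if (!is.null(col_meta$AffinityKd))
      .parse_numeric_col(col_meta$AffinityKd, "AffinityKd", path)
      else rep(1, p),
    stringsAsFactors = FALSE
  )
  list(long = long, annotation = annotation)
}

#' Write pipeline results to a report directory
#'
#' Emits the standard result files: cluster assignments, the k-selection vote
#' table, stability report, driver statistics, survival summary, and a JSON
#' run manifest recording every seed, configuration choice and warning.
#' Identical inputs produce byte-identical TSV files.
#'
#' @param results a named list; recognised elements are `solution`
#'   (cluster solution), `k_selection`, `stability`, `drivers` (data frame),
#'   `survival_summary` (data frame) and `manifest` (list).
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(results, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2L) != 0L)
    stop(sprintf("cannot write to directory '%s'", dir), call. = FALSE)
  files <- character(0)
  put <- function(df, name) {
    f <- file.path(dir, name)
    .write_tsv(df, f)
    files <<- c(files, f)
  }
  if (!is.null(results$solution)) {
    sol <- results$solution
    put(data.frame(patient_id = names(sol$labels),
                   cluster = as.integer(sol$labels),
                   stringsAsFactors = FALSE), "cluster_assignments.tsv")
  }
  if (!is.null(results$k_selection)) {
    ks <- results$k_selection
    put(data.frame(k = as.integer(names(ks$votes)),
                   votes = as.integer(ks$votes),
                   stringsAsFactors = FALSE), "k_selection.tsv")
  }
  if (!is.null(results$stability)) {
    st <- results$stability
    put(data.frame(cluster = seq_along(st$mean_jaccard),
                   mean_jaccard = st$mean_jaccard,
                   stable = st$stable,
                   stringsAsFactors = FALSE), "stability.tsv")
  }
  if (!is.null(results$drivers)) put(results$drivers, "driver_statistics.tsv")
  if (!is.null(results$survival_summary))
    put(results$survival_summary, "survival_summary.tsv")
  manifest <- results$manifest %||% list()
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, mf)
  invisible(files)
}

#' Validate a run manifest against the bundled JSON schema
#'
#' A small structural validator supporting the `type`, `required` and
#' `properties` keywords of the bundled schema (enough to pin the manifest
#' contract without a full JSON-schema engine).
#'
#' @param manifest a manifest list or path to a manifest JSON file.
#' @param schema path to a JSON schema; defaults to the bundled one.
#' @return `TRUE` if valid, otherwise an error describing the first violation.
#' @export
validate_manifest <- function(manifest,
                              schema = system.file("extdata",
                                                   "manifest-schema.json",
                                                   package = "protraj")) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  sch <- jsonlite::read_json(schema, simplifyVector = FALSE)
  .check_schema(manifest, sch, "manifest")
  TRUE
}

.check_schema <- function(x, sch, where) {
  ty <- sch$type
  ok <- switch(ty %||% "any",
    object = is.list(x) && (is.null(names(x)) == (length(x) == 0L) ||
                              !is.null(names(x))),
    array = is.list(x) || (is.vector(x) && is.null(names(x))),
    string = is.character(x) && length(x) == 1L,
    number = is.numeric(x) && length(x) == 1L,
    integer = is.numeric(x) && length(x) == 1L && x == round(x),
    boolean = is.logical(x) && length(x) == 1L,
    any = TRUE
  )
  if (!isTRUE(ok))
    stop(sprintf("manifest schema violation at %s: expected %s", where, ty),
         call. = FALSE)
  if (identical(ty, "object")) {
    for (r in sch$required) {
      if (!r %in% names(x))
        stop(sprintf("manifest schema violation at %s: missing required '%s'",
                     where, r), call. = FALSE)
    }
    for (nm in names(sch$properties)) {
      if (nm %in% names(x))
        .check_schema(x[[nm]], sch$properties[[nm]],
                      paste(where, nm, sep = "."))
    }
  }
  invisible(TRUE)
}
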