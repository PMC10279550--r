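# Clinical characteristics across subphenotypes and the four pre-specified
# levels of Cox adjustment.

.pick_test <- function(values, groups, type, seed = 1L) {
  if (type == "numeric") {
    kt <- kruskal.test(values, factor(groups))
    return(list(test = "kruskal_wallis", statistic = unname(kt$statistic),
                p = unname(kt$p.value)))
  }
  tab <- table(values, groups)
  exp_counts <- suppressWarnings(chisq.test(tab, correct = FALSE)$expected)
  if (any(exp_counts < 5)) {
    ft <- if (all(dim(tab) == c(2L, 2L))) fisher.test(tab)
    else with_local_seed(seed, fisher.test(tab, simulate.p.value = TRUE,
                                           B = 10000L))
    list(test = "fisher_exact", statistic = NA_real_, p = unname(ft$p.value))
  } else {
    ct <- chisq.test(tab, correct = FALSE)
    list(test = "chi_square", statistic = unname(ct$statistic),
         p = unname(ct$p.value))
  }
}

#' Compare clinical characteristics across subphenotypes
#'
#' Numeric variables are tested with Kruskal-Wallis; binary/categorical
#' variables with the chi-square test (no continuity correction), replaced by
#' Fisher's exact test whenever any expected cell count is below 5 (exact for
#' 2x2, simulated p-value with a fixed seed for larger tables). Variables
#' with a single distinct value are skipped and recorded.
#'
#' @param clinical clinical table with a `types` attribute (see
#'   [read_clinical_table()]).
#' @param labels named subphenotype labels covering every patient.
#' @param seed seed for simulated Fisher p-values.
#' @return Object of class `clinical_comparison`: a data frame of variable,
#'   test, statistic, p, plus per-group summaries and `skipped`.
#' @export
compare_clinical <- function(clinical, labels, seed = 1L) {
  types <- attr(clinical, "types")
  if (is.null(types)) stop("clinical table lacks a 'types' attribute",
                           call. = FALSE)
  g <- labels[clinical$patient_id]
  if (any(is.na(g))) stop("labels must cover all patients", call. = FALSE)
  rows <- list(); summaries <- list(); skipped <- character(0)
  for (v in names(types)) {
    if (!v %in% names(clinical)) next
    x <- clinical[[v]]
    if (length(unique(x)) < 2L) { skipped <- c(skipped, v); next }
    res <- .pick_test(x, g, if (types[[v]] == "numeric") "numeric" else
      "categorical", seed = derive_seed(seed, paste0("fisher-", v)))
    rows[[v]] <- data.frame(variable = v, type = types[[v]], test = res$test,
                            statistic = res$statistic, p = res$p,
                            stringsAsFactors = FALSE)
    summaries[[v]] <- if (types[[v]] == "numeric") {
      t(vapply(split(x, g), function(xx)
        c(median = median(xx), q1 = unname(quantile(xx, 0.25)),
          q3 = unname(quantile(xx, 0.75))), numeric(3)))
    } else {
      t(vapply(split(x, g), function(xx)
        c(count = sum(xx == max(x)), percent = 100 * mean(xx == max(x))),
        numeric(2)))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, group_summaries = summaries, skipped = skipped),
            class = "clinical_comparison")
}

#' @export
print.clinical_comparison <- function(x, ...) {
  cat("Clinical comparisons across subphenotypes:\n")
  print(x$table, row.names = FALSE)
  if (length(x$skipped))
    cat("skipped (single value):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Select the data-driven adjustment covariates (model 3)
#'
#' Tests every clinical variable against endpoint occurrence (numeric:
#' Kruskal-Wallis by event status; categorical: chi-square/Fisher by the
#' small-cell rule), adjusts across variables with Benjamini-Hochberg, keeps
#' those with q < `alpha`, and always includes the forced trio (age, sex,
#' eGFR by default) regardless of significance.
#'
#' @param clinical clinical table with `types`.
#' @param outcomes outcome table.
#' @param forced variables always retained.
#' @param alpha FDR level.
#' @param seed seed for simulated Fisher p-values.
#' @return Character vector of covariate names, with a `tests` attribute
#'   (the per-variable p/q table).
#' @export
select_model3_covariates <- function(clinical, outcomes,
                                     forced = c("age", "sex", "egfr"),
                                     alpha = 0.05, seed = 1L) {
  types <- attr(clinical, "types")
  ev <- setNames(outcomes$event, outcomes$patient_id)[clinical$patient_id]
  vars <- intersect(names(types), names(clinical))
  p <- setNames(rep(NA_real_, length(vars)), vars)
  for (v in vars) {
    x <- clinical[[v]]
    if (length(unique(x)) < 2L || length(unique(ev)) < 2L) next
    res <- .pick_test(x, ev, if (types[[v]] == "numeric") "numeric" else
      "categorical", seed = derive_seed(seed, paste0("m3-", v)))
    p[v] <- res$p
  }
  ok <- !is.na(p)
  q <- setNames(rep(NA_real_, length(p)), names(p))
  if (any(ok)) q[ok] <- bh_adjust(p[ok], q = alpha)$q_values
  selected <- names(q)[!is.na(q) & q < alpha]
  out <- union(forced, selected)
  attr(out, "tests") <- data.frame(variable = vars, p = p, q = q,
                                   row.names = NULL, stringsAsFactors = FALSE)
  out
}

# Build the design matrix for a given adjustment level.
.build_design <- function(labels, clinical, covariates, log_ntprobnp = NULL) {
  g <- factor(labels[clinical$patient_id])
  X <- stats::model.matrix(~ g)[, -1L, drop = FALSE]
  colnames(X) <- paste0("subpheno", levels(g)[-1L])
  types <- attr(clinical, "types")
  for (v in covariates) {
    if (!v %in% names(clinical))
      stop(sprintf("covariate '%s' not in clinical table", v), call. = FALSE)
    if (!is.null(types) && types[[v]] == "categorical") {
      f <- factor(clinical[[v]])
      M <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
      colnames(M) <- paste0(v, levels(f)[-1L])
      X <- cbind(X, M)
    } else {
      X <- cbind(X, matrix(clinical[[v]], ncol = 1L,
                           dimnames = list(NULL, v)))
    }
  }
  if (!is.null(log_ntprobnp)) X <- cbind(X, log_ntprobnp = log_ntprobnp)
  rownames(X) <- clinical$patient_id
  as.matrix(X)
}

#' Fit the four pre-specified levels of Cox adjustment
#'
#' Level 1 enters the subphenotype dummies alone (reference: subphenotype 1);
#' level 2 adds age, sex and eGFR; level 3 adds every clinical variable
#' significantly associated with the endpoint after Benjamini-Hochberg
#' correction (with the age/sex/eGFR trio forced in); level 4 adds
#' log-transformed NT-proBNP. Each fit reports hazard ratios, AIC/BIC and
#' apparent plus optimism-corrected concordance.
#'
#' @param labels named subphenotype labels.
#' @param clinical clinical table with `types`.
#' @param outcomes outcome table.
#' @param levels which model levels to fit.
#' @param forced the forced covariate trio.
#' @param ntprobnp_var name of the NT-proBNP column (entered as its natural
#'   log in level 4).
#' @param B bootstrap replicates for the optimism correction.
#' @param seed integer seed.
#' @return Object of class `cox_levels`: per-level `cox_fit`s, concordance
#'   results and a summary data frame.
#' @export
cox_adjustment_levels <- function(labels, clinical, outcomes,
                                  levels = 1:4,
                                  forced = c("age", "sex", "egfr"),
                                  ntprobnp_var = "ntprobnp",
                                  B = 200L, seed = 1L) {
  ord <- match(clinical$patient_id, outcomes$patient_id)
  time <- outcomes$time_to_event_years[ord]
  event <- outcomes$event[ord]
  m3 <- select_model3_covariates(clinical, outcomes, forced = forced,
                                 seed = derive_seed(seed, "model3"))
  m3 <- setdiff(m3, ntprobnp_var)  # NT-proBNP enters only at level 4
  covsets <- list(
    `1` = character(0),
    `2` = forced,
    `3` = m3,
    `4` = m3
  )
  fits <- list(); summaries <- list(); cstats <- list()
  for (lev in levels) {
    covs <- covsets[[as.character(lev)]]
    lognt <- if (lev == 4L) log(clinical[[ntprobnp_var]]) else NULL
    X <- .build_design(labels, clinical, covs, log_ntprobnp = lognt)
    fit <- fit_cox(X, time, event)
    cc <- optimism_corrected_c(X, time, event, B = B,
                               seed = derive_seed(seed, paste0("optimism-", lev)))
    fits[[as.character(lev)]] <- fit
    cstats[[as.character(lev)]] <- cc
    sub_idx <- grep("^subpheno", names(fit$coef))
    summaries[[as.character(lev)]] <- data.frame(
      level = lev,
      covariates = paste(c("subphenotype", covs,
                           if (lev == 4L) "log_ntprobnp"), collapse = "+"),
      term = names(fit$coef)[sub_idx],
      hr = unname(fit$hr[sub_idx]),
      ci_lower = unname(fit$ci_lower[sub_idx]),
      ci_upper = unname(fit$ci_upper[sub_idx]),
      p = unname(fit$p[sub_idx]),
      AIC = fit$AIC, BIC = fit$BIC,
      apparent_c = cc$apparent, corrected_c = cc$corrected,
      stringsAsFactors = FALSE
    )
  }
  structure(list(fits = fits, concordance = cstats,
                 summary = do.call(rbind, c(summaries, make.row.names = FALSE)),
                 model3_covariates = m3),
            class = "cox_levels")
}

#' @export
print.cox_levels <- function(x, ...) {
  cat("Cox proportional-hazards models (four adjustment levels):\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
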