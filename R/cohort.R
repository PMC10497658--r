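# Cohort-level statistics: group comparisons, ILI-displacement correlation
# and regression, displacement-cutoff subset analysis, symptom contrasts.
#
# Subject records are plain data frames with columns
#   id, group ("CMI"/"control"), ili_dyn_cm5, disp_cerebellum_um,
#   disp_brainstem_um, and optionally the five symptom flags
#   (imbalance, vertigo, swallowing, nausea_vomiting, hoarseness)
#   plus mpq and diq questionnaire scores.

MEASURE_COLS <- c("ili_dyn_cm5", "disp_cerebellum_um", "disp_brainstem_um")
SYMPTOM_COLS <- c("imbalance", "vertigo", "swallowing", "nausea_vomiting",
                  "hoarseness")

validate_records <- function(records) {
  need <- c("id", "group", MEASURE_COLS)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing columns: ", paste(miss, collapse = ", "))
  if (!all(records$group %in% c("CMI", "control")))
    stop("group must be 'CMI' or 'control'")
  if (any(records$ili_dyn_cm5 <= 0, na.rm = TRUE))
    stop("ILI values must be positive")
  if (any(records$disp_cerebellum_um < 0, na.rm = TRUE) ||
      any(records$disp_brainstem_um < 0, na.rm = TRUE))
    stop("displacements must be non-negative")
  invisible(records)
}

#' Welch's unpaired t-test (unequal variances)
#'
#' Thin wrapper around [stats::t.test()] with Satterthwaite degrees of
#' freedom and a p = 1 convention when both groups are constant with equal
#' means (zero evidence of a difference).
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @return list with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`.
#' @export
welch_t_test <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 finite values")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(statistic = 0, df = NA_real_, p_value = 1,
                  mean_a = mean(group_a), mean_b = mean(group_b),
                  n_a = length(group_a), n_b = length(group_b)))
    return(list(statistic = sign(mean(group_a) - mean(group_b)) * Inf,
                df = NA_real_, p_value = 0,
                mean_a = mean(group_a), mean_b = mean(group_b),
                n_a = length(group_a), n_b = length(group_b)))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(group_a), mean_b = mean(group_b),
       n_a = length(group_a), n_b = length(group_b))
}

#' Pearson correlation with linear regression (non-zero intercept)
#'
#' Pearson r with its two-sided t-distribution p-value, plus ordinary least
#' squares `y ~ x` with 95% confidence intervals on slope and intercept.
#'
#' @param x,y numeric vectors of equal length (n >= 3, finite, non-constant).
#' @return list with `r`, `p_value`, `slope`, `intercept`, `slope_ci`,
#'   `intercept_ci`, `n`.
#' @export
pearson_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  # suppress the "essentially perfect fit" note when points are collinear
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       slope_ci = unname(ci[2L, ]), intercept_ci = unname(ci[1L, ]),
       n = length(x))
}

#' Shapiro-Wilk normality test
#'
#' Delegates to [stats::shapiro.test()] after validating the sample size
#' (3 to 5000) and rejecting constant input.
#'
#' @param values numeric vector.
#' @return list with `statistic` and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || length(values) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", length(values), ")")
  if (stats::sd(values) == 0) stop("Shapiro-Wilk undefined for constant input")
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Displacement-cutoff subset regressions for CMI subjects
#'
#' For each cutoff c, restricts the CMI group to subjects with cerebellar
#' displacement strictly greater than c and regresses displacement on ILI;
#' reports (cutoff, n, r, p). An "all cases" row (cutoff -Inf) is included
#' first. Subsets smaller than 3 yield NA (not computable). Ties exactly at
#' a cutoff are counted in `n_ties`.
#'
#' @param records subject records data frame.
#' @param cutoffs displacement cutoffs in um; default `c(150, 200, 250)`.
#' @param region "cerebellum" (default) or "brainstem".
#' @return data.frame with columns `cutoff_um`, `n`, `n_ties`, `r`, `p`.
#' @export
cutoff_subset_analysis <- function(records, cutoffs = c(150, 200, 250),
                                   region = "cerebellum") {
  validate_records(records)
  col <- paste0("disp_", region, "_um")
  cmi <- records[records$group == "CMI", ]
  rows <- lapply(c(-Inf, sort(cutoffs)), function(cf) {
    sub <- cmi[cmi[[col]] > cf, ]
    ties <- sum(cmi[[col]] == cf)
    if (nrow(sub) < 3L)
      return(data.frame(cutoff_um = cf, n = nrow(sub), n_ties = ties,
                        r = NA_real_, p = NA_real_))
    pr <- pearson_regression(sub$ili_dyn_cm5, sub[[col]])
    data.frame(cutoff_um = cf, n = pr$n, n_ties = ties, r = pr$r,
               p = pr$p_value)
  })
  do.call(rbind, rows)
}

#' Compare biomechanical measures between symptom arms
#'
#' Welch t-tests of ILI, cerebellar and brainstem displacement between CMI
#' subjects with and without the named symptom. Subjects with a missing flag
#' are excluded.
#'
#' @param records subject records data frame.
#' @param symptom flag column name, one of imbalance, vertigo, swallowing,
#'   nausea_vomiting, hoarseness (or any logical column present).
#' @param p_adjust "none" (default, mirroring the uncorrected analysis) or
#'   "bonferroni" across the three measures.
#' @return data.frame with one row per measure: means, t, df, p, arm sizes.
#' @export
symptom_comparison <- function(records, symptom,
                               p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  validate_records(records)
  if (!symptom %in% names(records))
    stop("symptom column '", symptom, "' not present")
  cmi <- records[records$group == "CMI" & !is.na(records[[symptom]]), ]
  pos <- cmi[cmi[[symptom]] == TRUE, ]
  neg <- cmi[cmi[[symptom]] == FALSE, ]
  if (nrow(pos) < 2L || nrow(neg) < 2L)
    stop("symptom '", symptom, "' has an arm with fewer than 2 subjects (",
         nrow(pos), " with, ", nrow(neg), " without)")
  if (nrow(pos) < 4L || nrow(neg) < 4L)
    warning("symptom '", symptom, "' has an arm with fewer than 4 subjects")
  rows <- lapply(MEASURE_COLS, function(m) {
    wt <- welch_t_test(pos[[m]], neg[[m]])
    data.frame(measure = m, mean_with = wt$mean_a, mean_without = wt$mean_b,
               t = wt$statistic, df = wt$df, p = wt$p_value,
               n_with = wt$n_a, n_without = wt$n_b)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "bonferroni")
    out$p_adjusted <- stats::p.adjust(out$p, method = "bonferroni")
  out
}

#' Per-group summary and CMI vs control comparison
#'
#' Group means and SDs of each biomechanical measure, Welch t-tests between
#' groups, and Shapiro-Wilk normality p-values per group and measure.
#'
#' @param records subject records data frame.
#' @return list with data frames `groups` and `comparison`.
#' @export
cohort_summary <- function(records) {
  validate_records(records)
  groups <- do.call(rbind, lapply(c("CMI", "control"), function(g) {
    sub <- records[records$group == g, ]
    do.call(rbind, lapply(MEASURE_COLS, function(m) {
      v <- sub[[m]][is.finite(sub[[m]])]
      sw <- tryCatch(shapiro_wilk(v)$p_value, error = function(e) NA_real_)
      data.frame(group = g, measure = m, n = length(v), mean = mean(v),
                 sd = stats::sd(v), shapiro_p = sw)
    }))
  }))
  comparison <- do.call(rbind, lapply(MEASURE_COLS, function(m) {
    wt <- welch_t_test(records[[m]][records$group == "CMI"],
                       records[[m]][records$group == "control"])
    data.frame(measure = m, mean_cmi = wt$mean_a, mean_control = wt$mean_b,
               t = wt$statistic, df = wt$df, p = wt$p_value)
  }))
  list(groups = groups, comparison = comparison)
}

#' Full cohort statistical report
#'
#' Assembles the group comparison, the per-group ILI-displacement
#' correlations for both brain regions, the displacement-cutoff subset
#' table, the five symptom contrasts (where flags are present) and optional
#' questionnaire correlations.
#'
#' @param records subject records data frame.
#' @param cutoffs displacement cutoffs in um for the subset analysis.
#' @return An object of class `cohort_report` (a list of data frames).
#' @export
cohort_report <- function(records, cutoffs = c(150, 200, 250)) {
  validate_records(records)
  correlations <- do.call(rbind, lapply(c("CMI", "control"), function(g) {
    sub <- records[records$group == g, ]
    do.call(rbind, lapply(c("cerebellum", "brainstem"), function(rg) {
      pr <- tryCatch(
        pearson_regression(sub$ili_dyn_cm5, sub[[paste0("disp_", rg, "_um")]]),
        error = function(e) NULL)
      if (is.null(pr)) return(NULL)
      data.frame(group = g, region = rg, n = pr$n, r = pr$r, p = pr$p_value,
                 slope = pr$slope, intercept = pr$intercept,
                 slope_lo = pr$slope_ci[1L], slope_hi = pr$slope_ci[2L])
    }))
  }))
  symptoms <- NULL
  have_flags <- intersect(SYMPTOM_COLS, names(records))
  for (s in have_flags) {
    tab <- tryCatch(symptom_comparison(records, s), error = function(e) NULL)
    if (!is.null(tab)) { tab$symptom <- s; symptoms <- rbind(symptoms, tab) }
  }
  pain <- NULL
  for (qc in intersect(c("mpq", "diq"), names(records))) {
    sub <- records[records$group == "CMI" & is.finite(records[[qc]]), ]
    if (nrow(sub) >= 3L) {
      pain <- rbind(pain, do.call(rbind, lapply(MEASURE_COLS, function(m) {
        pr <- tryCatch(pearson_regression(sub[[m]], sub[[qc]]),
                       error = function(e) NULL)
        if (is.null(pr)) return(NULL)
        data.frame(score = qc, measure = m, n = pr$n, r = pr$r, p = pr$p_value)
      })))
    }
  }
  summ <- cohort_summary(records)
  structure(list(groups = summ$groups, comparison = summ$comparison,
                 correlations = correlations,
                 cutoff_table = cutoff_subset_analysis(records, cutoffs),
                 symptom_table = symptoms, pain_table = pain),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report\n=============\n\nGroup comparison (Welch):\n")
  print(x$comparison, row.names = FALSE)
  cat("\nILI-displacement correlations:\n")
  print(x$correlations, row.names = FALSE)
  cat("\nCerebellar displacement cutoff subsets (CMI):\n")
  print(x$cutoff_table, row.names = FALSE)
  if (!is.null(x$symptom_table)) {
    cat("\nSymptom contrasts: ", length(unique(x$symptom_table$symptom)),
        " symptoms tested, ",
        sum(x$symptom_table$p < 0.05), " of ", nrow(x$symptom_table),
        " measure comparisons significant at 0.05\n", sep = "")
  }
  invisible(x)
}

#' Read subject records from CSV
#' @param path CSV with the standard cohort columns.
#' @return Validated records data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path)
  for (s in intersect(SYMPTOM_COLS, names(df))) df[[s]] <- as.logical(df[[s]])
  validate_records(df)
  df
}

#' Write subject records to CSV
#' @param records records data frame.
#' @param path output path.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
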