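#' Single-pass outlier mask at k standard deviations from the mean
#'
#' Returns a keep-mask excluding values farther than `threshold_sd` sample
#' standard deviations (n-1 denominator) from the mean, in a single pass
#' (excluded values are not re-entered into the mean/sd). With fewer than 3
#' values nothing is excluded (the sd is undefined or uninformative).
#'
#' @param values Numeric vector.
#' @param threshold_sd Exclusion threshold in sd units (default 2).
#' @return Logical vector, `TRUE` = keep. `NA` values are dropped (mask
#'   `FALSE`) but do not enter the mean/sd.
#' @export
exclude_outliers <- function(values, threshold_sd = 2) {
  stopifnot(length(values) >= 1)
  ok <- !is.na(values)
  if (sum(ok) < 3) return(ok)
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  if (s == 0) return(ok)
  ok & abs(values - m) <= threshold_sd * s
}

#' Pooled-variance two-sample t-test with Cohen's d
#'
#' Student's t with the pooled variance estimate,
#' `df = n_a + n_b - 2`, two-tailed p, and Cohen's d computed as
#' `(mean_a - mean_b) / pooled sd` (n-1 denominators).
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @param name Label for the comparison.
#' @return data.frame (`stat_result`): `name`, `statistic`, `df`, `p_raw`,
#'   `effect_size`, `effect_size_kind = "cohens_d"`.
#' @export
two_sample_t <- function(a, b, name = "a_vs_b") {
  stopifnot(length(a) >= 2, length(b) >= 2)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    if (mean(a) != mean(b)) stop("zero pooled variance with unequal means: t is infinite")
    tt <- list(statistic = c(t = 0), parameter = c(df = length(a) + length(b) - 2),
               p.value = 1)
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE)
  }
  d <- if (sp2 == 0) 0 else (mean(a) - mean(b)) / sqrt(sp2)
  res <- data.frame(name = name, statistic = unname(tt$statistic),
                    df = unname(tt$parameter), p_raw = tt$p.value,
                    effect_size = d, effect_size_kind = "cohens_d",
                    stringsAsFactors = FALSE)
  class(res) <- c("stat_result", "data.frame")
  res
}

#' Pearson correlation with the df = n - 2 t-transform p-value
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @param name Label for the comparison.
#' @return data.frame (`stat_result`): `statistic` is r, `df = n - 2`,
#'   two-tailed `p_raw`, `effect_size = r`.
#' @export
pearson_r <- function(x, y, name = "x_vs_y") {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  res <- data.frame(name = name, statistic = unname(ct$estimate),
                    df = unname(ct$parameter), p_raw = ct$p.value,
                    effect_size = unname(ct$estimate), effect_size_kind = "r",
                    stringsAsFactors = FALSE)
  class(res) <- c("stat_result", "data.frame")
  res
}

#' Bonferroni correction
#'
#' `min(1, p * m)` for a family of `m` comparisons.
#'
#' @param p_raw Raw p-value(s) in `[0, 1]`.
#' @param m Family size (>= 1).
#' @return Corrected p-value(s).
#' @export
bonferroni <- function(p_raw, m) {
  stopifnot(all(p_raw >= 0 & p_raw <= 1, na.rm = TRUE), m >= 1)
  pmin(1, p_raw * m)
}

#' Two-by-two mixed-design ANOVA with partial eta squared
#'
#' Classical split-plot decomposition for one between-subjects factor
#' (`group`, 2 levels) crossed with one within-subjects factor (`time`, 2
#' levels, both observed on every subject). The between effect is tested
#' against the subject-within-group error stratum; the within effect and the
#' interaction against the time-by-subject error. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with each effect's own error term.
#'
#' @param design_table data.frame with columns `subject_id`, `group`, `time`,
#'   `value`; exactly one value per subject per time level, no imputation.
#' @return data.frame (`stat_result`), rows `group`, `time`, `group:time`,
#'   with `statistic` = F, `df` = "df1,df2", `p_raw` and
#'   `effect_size` = partial eta squared. Attribute `ss` carries the full
#'   sums-of-squares table.
#' @export
mixed_anova_2x2 <- function(design_table) {
  req <- c("subject_id", "group", "time", "value")
  if (!all(req %in% names(design_table))) {
    stop("design_table needs columns: ", paste(req, collapse = ", "))
  }
  counts <- table(design_table$subject_id, design_table$time)
  if (any(counts != 1)) {
    stop("each subject needs exactly one value per time level (no imputation)")
  }
  g_per_subj <- tapply(design_table$group, design_table$subject_id,
                       function(g) length(unique(g)))
  if (any(g_per_subj != 1)) stop("each subject must belong to exactly one group")

  df <- data.frame(subject_id = factor(design_table$subject_id),
                   group = factor(design_table$group),
                   time = factor(design_table$time),
                   value = design_table$value)
  fit <- stats::aov(value ~ group * time + Error(subject_id / time), data = df)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject_id"]][[1]])
  within <- as.data.frame(sm[["Error: subject_id:time"]][[1]])
  row_of <- function(tab, pat) tab[grep(pat, trimws(rownames(tab)))[1], ]
  g_row <- row_of(between, "^group$")
  sw_row <- row_of(between, "^Residuals$")
  t_row <- row_of(within, "^time$")
  gt_row <- row_of(within, "^group:time$")
  tw_row <- row_of(within, "^Residuals$")

  mk <- function(name, eff, err) {
    data.frame(name = name, statistic = eff[["F value"]],
               df = sprintf("%d,%d", eff$Df, err$Df),
               p_raw = eff[["Pr(>F)"]],
               effect_size = if (eff[["Sum Sq"]] + err[["Sum Sq"]] == 0) 0 else
                 eff[["Sum Sq"]] / (eff[["Sum Sq"]] + err[["Sum Sq"]]),
               effect_size_kind = "partial_eta_sq", stringsAsFactors = FALSE)
  }
  res <- rbind(mk("group", g_row, sw_row),
               mk("time", t_row, tw_row),
               mk("group:time", gt_row, tw_row))
  # all-constant data: aov reports NaN F; define SS_effect = 0 => F = 0
  res$statistic[is.na(res$statistic) | is.nan(res$statistic)] <- 0
  res$p_raw[is.na(res$p_raw)] <- 1
  attr(res, "ss") <- data.frame(
    term = c("group", "subject_within_group", "time", "group:time",
             "time:subject_within_group"),
    ss = c(g_row[["Sum Sq"]], sw_row[["Sum Sq"]], t_row[["Sum Sq"]],
           gt_row[["Sum Sq"]], tw_row[["Sum Sq"]]),
    df = c(g_row$Df, sw_row$Df, t_row$Df, gt_row$Df, tw_row$Df)
  )
  class(res) <- c("stat_result", "data.frame")
  res
}

#' Two-group comparison report over a measure table
#'
#' For each requested measure: per-group single-pass outlier exclusion
#' ([exclude_outliers()]), pooled two-sample t with Cohen's d, and Bonferroni
#' correction over the measure family. Mirrors a cross-sectional two-group
#' analysis phase.
#'
#' @param measure_table data.frame with a `group` column (exactly two levels)
#'   and one numeric column per measure, e.g. from [analyze_cohort()].
#' @param measures Character vector of measure column names; default all
#'   numeric columns except identifiers.
#' @param threshold_sd Outlier threshold in sd units; `Inf` disables
#'   exclusion.
#' @param bonferroni_m Family size; default the number of measures. With
#'   `m = 1` the corrected p is omitted (`NA`).
#' @return data.frame: one row per measure with `measure`, `contrast`,
#'   `statistic`, `df`, `p_raw`, `p_corrected`, `effect_size`,
#'   `effect_size_kind`, `n_a`, `n_b` (after exclusion), `n_excluded`.
#' @export
compare_groups <- function(measure_table, measures = NULL, threshold_sd = 2,
                           bonferroni_m = NULL) {
  stopifnot("group" %in% names(measure_table))
  groups <- unique(measure_table$group)
  if (length(groups) != 2) stop("measure_table must contain exactly two groups")
  numeric_cols <- names(measure_table)[vapply(measure_table, is.numeric, TRUE)]
  known <- setdiff(numeric_cols, c("subject_id"))
  if (is.null(measures)) measures <- known
  bad <- setdiff(measures, known)
  if (length(bad)) {
    stop("unknown measure(s): ", paste(bad, collapse = ", "),
         "; known measures: ", paste(known, collapse = ", "))
  }
  m <- if (is.null(bonferroni_m)) length(measures) else bonferroni_m
  rows <- lapply(measures, function(ms) {
    a <- measure_table[measure_table$group == groups[1], ms]
    b <- measure_table[measure_table$group == groups[2], ms]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    keep_a <- if (is.finite(threshold_sd)) exclude_outliers(a, threshold_sd)
              else rep(TRUE, length(a))
    keep_b <- if (is.finite(threshold_sd)) exclude_outliers(b, threshold_sd)
              else rep(TRUE, length(b))
    tt <- two_sample_t(a[keep_a], b[keep_b], name = ms)
    data.frame(measure = ms,
               contrast = paste(groups[1], "vs", groups[2]),
               statistic = tt$statistic, df = tt$df, p_raw = tt$p_raw,
               p_corrected = if (m > 1) bonferroni(tt$p_raw, m) else NA_real_,
               effect_size = tt$effect_size,
               effect_size_kind = tt$effect_size_kind,
               n_a = sum(keep_a), n_b = sum(keep_b),
               n_excluded = sum(!keep_a) + sum(!keep_b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
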