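# Scan-rescan reproducibility statistics on ROI medians.
#
# Conventions (the usual ones in quantitative MRI repeatability work):
#   within-subject SD  sigma_w = sqrt(sum(d_i^2) / (2 n))
#   repeatability coef RC      = 1.96 * sqrt(2) * sigma_w
#   coefficient of variation   COV = 100 * sigma_w / grand mean
#   ICC: two-way random effects, absolute agreement, single measurement
#   Bland-Altman: bias = mean(d), LOA = bias +/- 1.96 * SD(d) (sample SD)
# with d_i = exam1_i - exam2_i.

#' Median of a map over an ROI mask
#'
#' @param map numeric matrix/array (NA = undefined voxel).
#' @param roi logical mask of the same shape.
#' @return median over in-mask, defined voxels.
#' @export
roi_median <- function(map, roi) {
  stopifnot(identical(dim(map), dim(roi)))
  if (!any(roi)) stop("empty ROI mask")
  stats::median(map[roi], na.rm = TRUE)
}

# coerce exam pairs: two-column matrix / data.frame or two vectors
.as_pairs <- function(exam1, exam2 = NULL) {
  if (is.null(exam2)) {
    p <- as.matrix(exam1)
    stopifnot(ncol(p) == 2L)
  } else {
    stopifnot(length(exam1) == length(exam2))
    p <- cbind(exam1, exam2)
  }
  p[stats::complete.cases(p), , drop = FALSE]
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' @param exam1,exam2 paired measurements (or a two-column matrix in
#'   `exam1`). Differences are exam1 - exam2.
#' @return list with `bias`, `loa_neg`, `loa_pos`, `sd_diff`, `n`.
#' @export
bland_altman <- function(exam1, exam2 = NULL) {
  p <- .as_pairs(exam1, exam2)
  if (nrow(p) < 2L) stop("need at least 2 pairs")
  d <- p[, 1L] - p[, 2L]
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_neg = bias - 1.96 * s, loa_pos = bias + 1.96 * s,
       sd_diff = s, n = nrow(p))
}

# sigma_w shared by RC and COV
.sigma_within <- function(p) sqrt(sum((p[, 1L] - p[, 2L])^2) / (2 * nrow(p)))

#' Repeatability coefficient
#' @inheritParams bland_altman
#' @return `1.96 * sqrt(2) * sigma_w`.
#' @export
repeatability_coefficient <- function(exam1, exam2 = NULL) {
  p <- .as_pairs(exam1, exam2)
  if (nrow(p) < 2L) stop("need at least 2 subjects")
  1.96 * sqrt(2) * .sigma_within(p)
}

#' Within-subject coefficient of variation (percent)
#' @inheritParams bland_altman
#' @return `100 * sigma_w / grand mean`.
#' @export
cov_percent <- function(exam1, exam2 = NULL) {
  p <- .as_pairs(exam1, exam2)
  if (nrow(p) < 2L) stop("need at least 2 subjects")
  g <- mean(p)
  if (g == 0) stop("grand mean is zero; COV undefined")
  100 * .sigma_within(p) / g
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement, from the
#' two-way ANOVA mean squares (subjects x exams).
#'
#' @inheritParams bland_altman
#' @return ICC in [-1, 1].
#' @export
icc_agreement <- function(exam1, exam2 = NULL) {
  p <- .as_pairs(exam1, exam2)
  n <- nrow(p); k <- ncol(p)
  if (n < 2L) stop("need at least 2 subjects")
  grand <- mean(p)
  row_m <- rowMeans(p)
  col_m <- colMeans(p)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((p - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Two-sided one-sample t test on exam differences
#'
#' @inheritParams bland_altman
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_bias_test <- function(exam1, exam2 = NULL) {
  p <- .as_pairs(exam1, exam2)
  if (nrow(p) < 2L) stop("need at least 2 subjects")
  d <- p[, 1L] - p[, 2L]
  n <- length(d)
  se <- stats::sd(d) / sqrt(n)
  tval <- if (se == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else mean(d) / se
  pval <- 2 * stats::pt(-abs(tval), df = n - 1)
  list(t = tval, p = pval, df = n - 1, mean_diff = mean(d))
}

#' Build an ROI value table
#'
#' @param subject,exam,roi,metric,value parallel vectors; `exam` in {1, 2}.
#' @return data frame of class `roi_table`; duplicates of
#'   (subject, exam, roi, metric) are an error.
#' @export
roi_table <- function(subject, exam, roi, metric, value) {
  df <- data.frame(subject = subject, exam = as.integer(exam), roi = roi,
                   metric = metric, value = value,
                   stringsAsFactors = FALSE)
  key <- interaction(df$subject, df$exam, df$roi, df$metric, drop = TRUE)
  if (anyDuplicated(key)) stop("duplicate (subject, exam, roi, metric) entry")
  class(df) <- c("roi_table", "data.frame")
  df
}

#' Per-ROI reproducibility report with mean row
#'
#' For every ROI (of one metric) computes exam means and SDs, Bland-Altman
#' bias and limits of agreement, repeatability coefficient, coefficient of
#' variation, ICC(2,1) and the paired bias test, then appends an `Mean` row
#' holding the unweighted arithmetic mean of each statistic across ROIs.
#' ROIs with incomplete exam pairs are skipped with a warning.
#'
#' @param table an [roi_table()] (or data frame with the same columns).
#' @param metric metric name to summarize (default: the only one present).
#' @return data frame of class `repro_report`.
#' @export
repro_summary <- function(table, metric = NULL) {
  if (is.null(metric)) {
    metric <- unique(table$metric)
    if (length(metric) != 1L) stop("multiple metrics; pick one")
  }
  tb <- table[table$metric == metric, , drop = FALSE]
  rois <- unique(tb$roi)
  rows <- list()
  for (r in rois) {
    sub <- tb[tb$roi == r, , drop = FALSE]
    wide <- merge(sub[sub$exam == 1L, c("subject", "value")],
                  sub[sub$exam == 2L, c("subject", "value")],
                  by = "subject", suffixes = c("_1", "_2"))
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
    if (nrow(wide) < 2L) {
      warning(sprintf("ROI '%s' skipped: incomplete exam pairs", r))
      next
    }
    e1 <- wide$value_1; e2 <- wide$value_2
    ba <- bland_altman(e1, e2)
    tt <- paired_bias_test(e1, e2)
    rows[[r]] <- data.frame(
      roi = r, n = nrow(wide),
      mean_exam1 = mean(e1), sd_exam1 = stats::sd(e1),
      mean_exam2 = mean(e2), sd_exam2 = stats::sd(e2),
      bias = ba$bias, loa_neg = ba$loa_neg, loa_pos = ba$loa_pos,
      rc = repeatability_coefficient(e1, e2),
      cov = cov_percent(e1, e2),
      icc = icc_agreement(e1, e2),
      t = tt$t, p = tt$p,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) stop("no ROI with complete pairs")
  rep_df <- do.call(rbind, rows)
  rownames(rep_df) <- NULL
  mean_row <- rep_df[1L, , drop = FALSE]
  mean_row$roi <- "Mean"
  num <- vapply(rep_df, is.numeric, logical(1))
  mean_row[, num] <- as.list(colMeans(rep_df[, num, drop = FALSE]))
  out <- rbind(rep_df, mean_row)
  rownames(out) <- NULL
  attr(out, "metric") <- metric
  class(out) <- c("repro_report", "data.frame")
  out
}

#' Mean row across already-summarized per-ROI statistics
#'
#' Computes the unweighted arithmetic mean of each numeric column of a
#' per-ROI statistics table (e.g. published per-ROI RC/COV/ICC values),
#' reproducing how summary "Mean" rows of reproducibility tables are formed.
#'
#' @param stats_table data frame with one row per ROI and numeric statistic
#'   columns.
#' @return one-row data frame of column means.
#' @export
mean_row <- function(stats_table) {
  num <- vapply(stats_table, is.numeric, logical(1))
  as.data.frame(as.list(colMeans(stats_table[, num, drop = FALSE])))
}

#' @export
print.repro_report <- function(x, digits = 3, ...) {
  cat(sprintf("reproducibility report (metric: %s)\n",
              attr(x, "metric") %||% "?"))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
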