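# Two-group channel statistics: pooled (equal-variance) Student's t,
# Benjamini-Hochberg FDR over the channel array, significance marks, and
# Spearman covariate correlations.

t_result <- function(t, df, mean_diff, se_diff) {
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 mean_diff = mean_diff, se_diff = se_diff),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %g, p = %.4g (mean diff %.4g, SE %.4g)\n",
              x$t, x$df, x$p, x$mean_diff, x$se_diff))
  invisible(x)
}

#' Two-sample pooled-variance Student's t-test
#'
#' Equal-variance form with \code{df = n1 + n2 - 2} and a two-tailed p from
#' the t distribution. Degenerate inputs with zero pooled variance yield
#' \code{t = 0, p = 1} when the means agree and an error otherwise.
#'
#' @param x,y Numeric sample vectors (each of length >= 2, finite).
#' @return A \code{t_test_result}: fields \code{t}, \code{df}, \code{p},
#'   \code{mean_diff} (x minus y), \code{se_diff}.
#' @export
t_two_sample <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per group")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite sample values")
  t_from_summary(mean(x), stats::sd(x), length(x),
                 mean(y), stats::sd(y), length(y), spread_kind = "sd")
}

#' Pooled t-test from summary statistics
#'
#' Identical contract to \code{\link{t_two_sample}} but starting from group
#' means and spreads, as printed in study summary tables. A spread given as
#' a standard error is converted back to a standard deviation via
#' \code{SD = SE * sqrt(n)}.
#'
#' @param m1,m2 Group means.
#' @param s1,s2 Group spreads (SD or SE per \code{spread_kind}).
#' @param n1,n2 Group sizes (>= 2).
#' @param spread_kind \code{"sd"} or \code{"se"}.
#' @return A \code{t_test_result}.
#' @export
t_from_summary <- function(m1, s1, n1, m2, s2, n2, spread_kind = c("sd", "se")) {
  spread_kind <- match.arg(spread_kind)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 values per group")
  if (any(c(s1, s2) < 0)) stop("spreads must be non-negative")
  if (spread_kind == "se") { s1 <- s1 * sqrt(n1); s2 <- s2 * sqrt(n2) }
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  diff <- m1 - m2
  if (sp2 == 0) {
    if (diff == 0) return(t_result(0, df, 0, 0))
    stop("degenerate variance: zero pooled variance with unequal means")
  }
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_result(diff / se, df, diff, se)
}

# Vectorized pooled t over matched columns of two subjects x channels
# matrices; returns a data.frame(t, df, p, mean_diff, se_diff) with one row
# per channel. Fast path shared by build_channel_table and the null
# calibration simulations.
channel_t_tests <- function(case, control) {
  stopifnot(is.matrix(case), is.matrix(control),
            ncol(case) == ncol(control))
  n1 <- nrow(case); n2 <- nrow(control)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 subjects per group")
  m1 <- colMeans(case); m2 <- colMeans(control)
  v1 <- colSums((case - rep(m1, each = n1))^2) / (n1 - 1)
  v2 <- colSums((control - rep(m2, each = n2))^2) / (n2 - 1)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  data.frame(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
             mean_diff = m1 - m2, se_diff = se,
             mean_case = m1, se_case = sqrt(v1 / n1),
             mean_control = m2, se_control = sqrt(v2 / n2))
}

#' Benjamini-Hochberg step-up false discovery rate procedure
#'
#' Sorts the p-values ascending, finds the largest k with
#' \code{p(k) <= k*q/m}, and rejects every hypothesis with
#' \code{p <= p(k)}. Under independent null p-values the expected
#' false-discovery proportion is bounded by q.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @param q FDR level in (0, 1), default 0.05.
#' @return List with \code{rejected} (logical vector aligned with
#'   \code{pvals}) and \code{threshold} (the critical p, 0 when nothing is
#'   rejected).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  m <- length(pvals)
  if (m == 0L) return(list(rejected = logical(0), threshold = 0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  ps <- sort(pvals)
  ok <- which(ps <= seq_len(m) * q / m)
  thr <- if (length(ok)) ps[max(ok)] else 0
  list(rejected = pvals <= thr & length(ok) > 0, threshold = thr)
}

#' Significance mark for a p-value
#'
#' Strict-inequality marks: \code{"**"} for p < 0.01, \code{"*"} for
#' p < 0.05, \code{"+"} (dagger) for p < 0.1, \code{"NS"} otherwise; the
#' FDR decision is carried independently of the mark.
#'
#' @param p P-value(s) in [0, 1].
#' @param alpha_marks Descending thresholds (dagger, star, double-star).
#' @return Character vector of marks.
#' @export
significance_mark <- function(p, alpha_marks = c(0.1, 0.05, 0.01)) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < alpha_marks[3], "**",
         ifelse(p < alpha_marks[2], "*",
                ifelse(p < alpha_marks[1], "+", "NS")))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Ranks with average ranks for ties, takes the Pearson correlation of the
#' ranks, and computes a two-tailed p from
#' \code{t = rho * sqrt((n-2)/(1-rho^2))} with \code{n - 2} degrees of
#' freedom; \code{rho = +/-1} is reported with the limiting p of 0.
#'
#' @param x,y Numeric vectors of equal length (n >= 3); pairs with any NA
#'   are dropped.
#' @return List with \code{rho}, \code{n}, \code{p}.
#' @export
spearman_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero rank variance: constant input vector")
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1 - 1e-15) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, n = n, p = p)
}

#' Two-tailed critical t value
#'
#' The Student-t quantile at \code{1 - alpha/2} (or \code{1 - alpha} when
#' one-tailed): the threshold |t| must exceed for significance at level
#' alpha. Strictly decreasing in both df and alpha.
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Significance level in (0, 1).
#' @param two_tailed Logical, default TRUE.
#' @return Numeric threshold.
#' @export
critical_t <- function(df, alpha, two_tailed = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  stats::qt(1 - alpha / (if (two_tailed) 2 else 1), df)
}

#' Channel-wise group comparison table
#'
#' Per channel: group means and standard errors of the subject task
#' statistics, the pooled t-test, the significance mark, and the
#' Benjamini-Hochberg FDR decision across all channels.
#'
#' @param case,control Subjects x channels matrices of per-subject channel
#'   statistics (mM*mm), channels aligned.
#' @param cfg An \code{analysis_config} (FDR level, mark thresholds).
#' @return A data.frame of class \code{channel_table} with columns
#'   \code{channel, mean_case, se_case, mean_control, se_control, t, df, p,
#'   mark, fdr}; the BH threshold is attached as attribute
#'   \code{"fdr_threshold"}.
#' @export
build_channel_table <- function(case, control, cfg = analysis_config()) {
  tt <- channel_t_tests(case, control)
  fdr <- bh_fdr(tt$p, cfg$fdr_q)
  out <- data.frame(channel = seq_len(nrow(tt)),
                    mean_case = tt$mean_case, se_case = tt$se_case,
                    mean_control = tt$mean_control,
                    se_control = tt$se_control,
                    t = tt$t, df = tt$df, p = tt$p,
                    mark = significance_mark(tt$p, cfg$alpha_marks),
                    fdr = fdr$rejected,
                    stringsAsFactors = FALSE)
  attr(out, "fdr_threshold") <- fdr$threshold
  class(out) <- c("channel_table", "data.frame")
  out
}

#' Demographic and behavioral group comparison table
#'
#' Group means and SDs with pooled two-tailed t-tests for age, full-scale
#' IQ, and the three Stroop correct-answer counts; tic severity (YGTSS) is
#' summarized for the case group only, with no between-group test.
#'
#' @param subjects A \code{subject_table} containing both groups.
#' @return A data.frame with one row per variable: \code{variable,
#'   mean_case, sd_case, mean_control, sd_control, t, df, p}.
#' @export
build_demographics_table <- function(subjects) {
  g <- split(subjects, subjects$group)
  if (is.null(g$case) || is.null(g$control)) stop("both groups must be present")
  if (nrow(g$case) < 2L || nrow(g$control) < 2L)
    stop("need at least 2 subjects per group")
  vars <- c(age = "age", fiq = "fiq", scwc1 = "scwc1", scwc2 = "scwc2",
            scwc3 = "scwc3")
  rows <- lapply(names(vars), function(v) {
    x <- g$case[[v]]; y <- g$control[[v]]
    if (all(is.na(x)) || all(is.na(y))) return(NULL)
    tt <- t_two_sample(x[!is.na(x)], y[!is.na(y)])
    data.frame(variable = v, mean_case = mean(x, na.rm = TRUE),
               sd_case = stats::sd(x, na.rm = TRUE),
               mean_control = mean(y, na.rm = TRUE),
               sd_control = stats::sd(y, na.rm = TRUE),
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  })
  ygtss <- g$case$ygtss
  if (!all(is.na(ygtss)))
    rows <- c(rows, list(data.frame(
      variable = "ygtss", mean_case = mean(ygtss, na.rm = TRUE),
      sd_case = stats::sd(ygtss, na.rm = TRUE),
      mean_control = NA_real_, sd_control = NA_real_,
      t = NA_real_, df = NA_integer_, p = NA_real_,
      stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}

#' Covariate correlation table
#'
#' Spearman correlations of the three Stroop correct-answer counts with
#' age, full-scale IQ, and (case group only) tic severity, computed within
#' each group.
#'
#' @param subjects A \code{subject_table}.
#' @return Data.frame with columns \code{group, covariate, scwc, rho, n, p,
#'   mark}.
#' @export
build_correlation_table <- function(subjects) {
  g <- split(subjects, subjects$group)
  rows <- list()
  for (grp in names(g)) {
    covs <- c("age", "fiq", if (grp == "case") "ygtss")
    for (cv in covs) for (sc in c("scwc1", "scwc2", "scwc3")) {
      x <- g[[grp]][[cv]]; y <- g[[grp]][[sc]]
      if (sum(is.finite(x) & is.finite(y)) < 3L) next
      r <- spearman_cor(x, y)
      rows[[length(rows) + 1L]] <-
        data.frame(group = grp, covariate = cv, scwc = sc, rho = r$rho,
                   n = r$n, p = r$p,
                   mark = significance_mark(r$p), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
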