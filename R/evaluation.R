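#' Range-normalized root-mean-square error
#'
#' \deqn{\mathrm{NRMSE} = \frac{\sqrt{\sum_i (\hat y_i - y_i)^2 / n}}
#'                             {y_{max} - y_{min}}}
#' where \eqn{n} is the number of compared points and the normalizer is the
#' range of the observed values. Lower values mean less residual variance;
#' multiply by 100 to quote as a percentage.
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 2).
#' @return NRMSE as a fraction (>= 0).
#' @examples
#' nrmse(c(1, 2, 3), c(1, 2, 4))  # 0.19245
#' @export
nrmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("`predicted` and `observed` must have equal length")
  if (length(observed) < 2L) stop("need at least 2 points")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)))
    stop("inputs must be finite")
  rng <- max(observed) - min(observed)
  if (rng <= 0) stop("observed values have zero range; NRMSE undefined")
  sqrt(mean((predicted - observed)^2)) / rng
}

#' Overlapping support of two binned distributions
#'
#' Restricts two distributions on the same bin grid to the bins where both
#' have positive mass, returning the paired proportions. This is the pairing
#' used before rank-based observer comparisons, which are only meaningful
#' where both observers actually responded.
#'
#' @param a,b [binned_distribution()] objects on the same grid (same width
#'   and phase).
#' @return A data.frame with columns `bin_center_deg`, `a`, `b`, one row per
#'   overlapping bin.
#' @export
overlap_points <- function(a, b) {
  al <- align_bins(a, b)
  keep <- al$a > 0 & al$b > 0
  if (!any(keep)) stop("distributions have no overlapping support")
  data.frame(bin_center_deg = al$bin_centers[keep],
             a = al$a[keep], b = al$b[keep])
}

#' Mann-Whitney U test with rank-biserial effect size
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test comparing two groups of
#' response proportions, with the rank-biserial correlation
#' \eqn{r_{rb} = 2U/(n_1 n_2) - 1}, where `U` is the statistic for the
#' first group `x`. Sign convention: `r_rb` is negative when `x` tends to
#' rank below `y`, positive when above, 0 at no stochastic dominance. The
#' test is exact when both groups have 10 or fewer untied observations;
#' otherwise the normal approximation with midranks and continuity
#' correction is used. Fully tied degenerate input yields p = 1 with
#' `degenerate = TRUE`.
#'
#' @param x,y Non-empty numeric vectors.
#' @return A list: `U`, `n1`, `n2`, `p`, `r_rb`, `degenerate`.
#' @examples
#' mann_whitney_rb(c(1, 2, 3), c(4, 5, 6))$r_rb  # -1
#' @export
mann_whitney_rb <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = n1 * n2 / 2, n1 = n1, n2 = n2, p = 1,
                r_rb = 0, degenerate = TRUE))
  }
  exact <- n1 <= 10 && n2 <= 10 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  U <- unname(wt$statistic)  # wilcox.test's W is the U statistic for x
  list(U = U, n1 = n1, n2 = n2, p = wt$p.value,
       r_rb = 2 * U / (n1 * n2) - 1, degenerate = FALSE)
}

#' Compare an observer's response distributions with a model prediction
#'
#' Builds the full model-evaluation report for the ventriloquist task: the
#' range-normalized RMSE between predicted and observed error distributions
#' in the visual-left and visual-right conditions (and their mean, the
#' overall NRMSE), plus Mann-Whitney/rank-biserial comparisons between two
#' observers on the bins where their distributions overlap.
#'
#' @param predicted_left,predicted_right Model-predicted
#'   [binned_distribution()]s per visual-offset condition.
#' @param observed_left,observed_right Observed distributions (first
#'   observer) per condition.
#' @param other_left,other_right Optional second observer's distributions;
#'   when given, Mann-Whitney comparisons first-vs-second observer are
#'   included per condition.
#' @return A `comparison_report` list: `nrmse_left`, `nrmse_right`,
#'   `nrmse_overall` (fractions), and optionally `mw_left`, `mw_right`
#'   (see [mann_whitney_rb()]).
#' @export
compare_distributions <- function(predicted_left, predicted_right,
                                  observed_left, observed_right,
                                  other_left = NULL, other_right = NULL) {
  one <- function(pred, obs) {
    al <- align_bins(pred, obs)
    nrmse(al$a, al$b)
  }
  rep <- list(nrmse_left = one(predicted_left, observed_left),
              nrmse_right = one(predicted_right, observed_right))
  rep$nrmse_overall <- mean(c(rep$nrmse_left, rep$nrmse_right))
  if (!is.null(other_left)) {
    ov <- overlap_points(observed_left, other_left)
    rep$mw_left <- mann_whitney_rb(ov$a, ov$b)
  }
  if (!is.null(other_right)) {
    ov <- overlap_points(observed_right, other_right)
    rep$mw_right <- mann_whitney_rb(ov$a, ov$b)
  }
  class(rep) <- "comparison_report"
  rep
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Model-observer comparison\n")
  cat(sprintf("  NRMSE: left %.2f%%, right %.2f%%, overall %.2f%%\n",
              100 * x$nrmse_left, 100 * x$nrmse_right, 100 * x$nrmse_overall))
  for (side in c("left", "right")) {
    mw <- x[[paste0("mw_", side)]]
    if (!is.null(mw))
      cat(sprintf("  Mann-Whitney (%s): U = %g, n1 = %d, n2 = %d, p = %.3g, r_rb = %.3f\n",
                  side, mw$U, mw$n1, mw$n2, mw$p, mw$r_rb))
  }
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' @param report A `comparison_report`.
#' @param path Output file path.
#' @export
write_comparison_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
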