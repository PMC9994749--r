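#' Localization-error distribution of a response set
#'
#' Computes the binned relative frequency of localization errors (reported
#' minus true position; for audiovisual trials, reported minus the tone
#' position) from a set of simulated or recorded responses.
#'
#' @param responses A `response_set` (see [simulate_unimodal()]).
#' @param bin_width_deg Bin width in degrees, default 3 (the module pitch).
#' @return A [binned_distribution()].
#' @export
error_distribution <- function(responses, bin_width_deg = 3) {
  if (!is.data.frame(responses) || nrow(responses) == 0L)
    stop("`responses` must be a non-empty response set")
  if (!"error_deg" %in% names(responses))
    stop("`responses` must have an `error_deg` column")
  bin_values(responses$error_deg, bin_width_deg)
}

#' Fit a Gaussian psychometric curve to a binned error distribution
#'
#' Fits the three-parameter Gaussian \eqn{a \exp(-(x - X)^2 / (2\sigma^2))}
#' to (bin center, proportion) pairs by Levenberg-Marquardt nonlinear least
#' squares. `X` is the curve's center — the most probable localization error
#' — and `sigma` its width — the perceptual variability. The amplitude is
#' left free because binned proportions need not integrate like a density.
#' Alongside the parameters the fit reports the coefficient of determination
#' R-squared (against the mean proportion) and an extra-sum-of-squares F
#' test of the Gaussian against the constant line y = k (the best constant
#' is the mean), \eqn{F = ((SS_k - SS_g)/2) / (SS_g / (n - 3))} on (2, n-3)
#' degrees of freedom: `better_than_constant` is `TRUE` when p < alpha.
#'
#' Starting values are the proportion-weighted mean and SD of the bin
#' centers and the maximum proportion; on convergence failure a fixed set of
#' perturbed restarts is tried before the fit is flagged as not converged.
#'
#' @param dist A [binned_distribution()] with at least 4 non-zero bins
#'   (three parameters must be identifiable).
#' @param alpha Significance level of the fit-versus-constant test.
#' @return An object of class `gaussian_fit` with components `X`, `sigma`,
#'   `amplitude`, `R2` (clipped to \[0, 1\], with `R2_clipped` flag), `F`,
#'   `p_value`, `better_than_constant`, `converged`, plus the data and
#'   fitted values. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @examples
#' x <- seq(-9, 9, by = 3)
#' y <- exp(-(x - 1)^2 / (2 * 4^2)); y <- y / sum(y)
#' fit <- fit_gaussian(binned_distribution(x, y))
#' coef(fit)
#' @export
fit_gaussian <- function(dist, alpha = 0.05) {
  stopifnot(inherits(dist, "binned_distribution"))
  x <- dist$bin_center_deg
  y <- dist$proportion
  if (sum(y > 0) < 4L)
    stop("need at least 4 non-zero bins to fit a 3-parameter Gaussian")
  n <- length(x)

  w <- y / sum(y)
  start <- list(a = max(y), X = sum(w * x),
                sigma = max(sqrt(sum(w * (x - sum(w * x))^2)),
                            attr(dist, "bin_width_deg") / 2, 0.1))
  fit1 <- try_gaussian_nls(x, y, start)
  if (is.null(fit1)) {
    # deterministic perturbed restarts
    perturb <- expand.grid(fa = c(0.5, 1, 2), fs = c(0.5, 1, 2),
                           dX = c(-1, 0, 1) * start$sigma)
    for (i in seq_len(nrow(perturb))) {
      st <- list(a = start$a * perturb$fa[i], X = start$X + perturb$dX[i],
                 sigma = start$sigma * perturb$fs[i])
      fit1 <- try_gaussian_nls(x, y, st)
      if (!is.null(fit1)) break
    }
  }
  converged <- !is.null(fit1)
  if (converged) {
    cf <- stats::coef(fit1)
    a <- unname(cf["a"]); X <- unname(cf["X"]); sigma <- abs(unname(cf["sigma"]))
    yhat <- a * exp(-(x - X)^2 / (2 * sigma^2))
  } else {
    a <- start$a; X <- start$X; sigma <- start$sigma
    yhat <- a * exp(-(x - X)^2 / (2 * sigma^2))
  }

  ss_g <- sum((y - yhat)^2)
  ss_k <- sum((y - mean(y))^2)
  R2_raw <- if (ss_k > 0) 1 - ss_g / ss_k else NA_real_
  R2_clipped <- isTRUE(R2_raw < 0)
  R2 <- if (is.na(R2_raw)) NA_real_ else min(max(R2_raw, 0), 1)
  df2 <- n - 3
  if (df2 > 0 && ss_g > .Machine$double.eps * ss_k) {
    Fstat <- ((ss_k - ss_g) / 2) / (ss_g / df2)
    p <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  } else if (df2 > 0 && ss_k > 0) {
    Fstat <- Inf; p <- 0  # essentially perfect fit
  } else {
    Fstat <- NA_real_; p <- NA_real_
  }

  structure(
    list(X = X, sigma = sigma, amplitude = a,
         R2 = R2, R2_clipped = R2_clipped,
         F = Fstat, p_value = p,
         better_than_constant = isTRUE(p < alpha),
         alpha = alpha, converged = converged,
         data = data.frame(bin_center_deg = x, proportion = y),
         fitted_values = yhat, df_residual = df2),
    class = "gaussian_fit")
}

try_gaussian_nls <- function(x, y, start) {
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - X)^2 / (2 * sigma^2)),
                      data = data.frame(x = x, y = y),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  if (any(!is.finite(cf)) || abs(cf["sigma"]) < 1e-8) return(NULL)
  fit
}

#' @export
print.gaussian_fit <- function(x, digits = 4, ...) {
  cat("Gaussian psychometric fit\n")
  cat(sprintf("  X = %s deg, sigma = %s deg, amplitude = %s\n",
              format(x$X, digits = digits), format(x$sigma, digits = digits),
              format(x$amplitude, digits = digits)))
  cat(sprintf("  R^2 = %s; fit vs y = k: F = %s, p = %s (%s)\n",
              format(x$R2, digits = digits), format(x$F, digits = digits),
              format.pval(x$p_value, digits = digits),
              if (x$better_than_constant) "better than constant"
              else "not better than constant"))
  if (!x$converged) cat("  WARNING: nonlinear fit did not converge; moment estimates reported\n")
  invisible(x)
}

#' @export
summary.gaussian_fit <- function(object, ...) {
  res <- stats::residuals(object)
  out <- list(fit = object,
              rse = sqrt(sum(res^2) / max(object$df_residual, 1)),
              n_bins = nrow(object$data))
  class(out) <- "summary.gaussian_fit"
  out
}

#' @export
print.summary.gaussian_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d bins, residual SE %s on %d df\n", x$n_bins,
              format(x$rse, digits = 4), x$fit$df_residual))
  invisible(x)
}

#' @export
coef.gaussian_fit <- function(object, ...) {
  c(X = object$X, sigma = object$sigma, amplitude = object$amplitude)
}

#' @export
fitted.gaussian_fit <- function(object, ...) object$fitted_values

#' @export
residuals.gaussian_fit <- function(object, ...) {
  object$data$proportion - object$fitted_values
}

#' Predict from a Gaussian psychometric fit
#'
#' @param object A `gaussian_fit`.
#' @param newdata Optional numeric vector of positions (degrees), or a
#'   data.frame with a `bin_center_deg` column; default = the fitted bins.
#' @param ... Unused.
#' @return Predicted proportions.
#' @export
predict.gaussian_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$bin_center_deg
       else if (is.data.frame(newdata)) newdata$bin_center_deg
       else as.numeric(newdata)
  object$amplitude * exp(-(x - object$X)^2 / (2 * object$sigma^2))
}

#' Plot a Gaussian psychometric fit
#'
#' Observed binned proportions with the fitted Gaussian curve overlaid.
#'
#' @param x A `gaussian_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gaussian_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$bin_center_deg, d$proportion,
                 xlab = "localization error (deg)",
                 ylab = "relative frequency", pch = 16, ...)
  xs <- seq(min(d$bin_center_deg), max(d$bin_center_deg), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = "magenta", lwd = 2)
  graphics::abline(v = x$X, lty = 3)
  invisible(x)
}

#' Serialize a Gaussian fit to JSON
#'
#' @param fit A `gaussian_fit`.
#' @param path Output file path.
#' @export
write_gaussian_fit <- function(fit, path) {
  rec <- list(X = fit$X, sigma = fit$sigma, amplitude = fit$amplitude,
              R2 = fit$R2, F = fit$F, p_value = fit$p_value,
              better_than_constant = fit$better_than_constant,
              converged = fit$converged)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
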