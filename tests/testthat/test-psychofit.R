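test_that("error distributions are counted and normalized correctly", {
  rs <- data.frame(error_deg = c(-3, 0, 0, 3))
  class(rs) <- c("response_set", "data.frame")
  d <- error_distribution(rs, bin_width_deg = 3)
  expect_equal(d$bin_center_deg, c(-3, 0, 3))
  expect_equal(d$proportion, c(0.25, 0.5, 0.25))
  # random input still sums to 1 and keeps interior zero bins
  rs2 <- data.frame(error_deg = c(-9, -9, 6, 0.2))
  class(rs2) <- c("response_set", "data.frame")
  d2 <- error_distribution(rs2, bin_width_deg = 3)
  expect_equal(sum(d2$proportion), 1)
  expect_equal(d2$bin_center_deg, seq(-9, 6, by = 3))
  expect_error(error_distribution(rs[0, , drop = FALSE]), "non-empty")
})

test_that("bin edges assign boundary values to the right-hand bin", {
  d <- bin_values(c(1.5, -1.5, 0), bin_width_deg = 3)
  # +1.5 is the right edge of the 0 bin -> bin centered at 3;
  # -1.5 is the right edge of the -3 bin -> bin centered at 0
  expect_equal(d$bin_center_deg, c(0, 3))
  expect_equal(d$proportion, c(2 / 3, 1 / 3))
})

test_that("noise-free Gaussian samples are recovered exactly", {
  # ordinates of the printed audiovisual visual-left fit at 3-degree bins
  X_true <- -11.235; s_true <- 2.04
  centers <- seq(-21, -3, by = 3)
  vals <- exp(-(centers - X_true)^2 / (2 * s_true^2))
  d <- binned_distribution(centers, vals / sum(vals))
  fit <- fit_gaussian(d)
  expect_equal(fit$X, X_true, tolerance = 1e-6)
  expect_equal(fit$sigma, s_true, tolerance = 1e-6)
  expect_equal(fit$R2, 1, tolerance = 1e-9)
  expect_true(fit$better_than_constant)
  expect_true(fit$converged)
})

test_that("a flat distribution is not better than the constant line", {
  d <- binned_distribution(seq(-9, 9, by = 3), rep(1 / 7, 7))
  fit <- fit_gaussian(d)
  expect_false(fit$better_than_constant)
})

test_that("fits require at least four informative bins", {
  d <- binned_distribution(c(-3, 0, 3), c(0.25, 0.5, 0.25))
  expect_error(fit_gaussian(d), "4 non-zero bins")
})

test_that("simulated human auditory data reproduce the printed fit parameters", {
  rs <- simulate_unimodal(pooled_design("auditory", 100),
                          observer_profile("human",
                                           report_granularity = "continuous"),
                          seed = 314)
  fit <- fit_gaussian(error_distribution(rs, bin_width_deg = 1))
  n <- nrow(rs)
  expect_lt(abs(fit$X - (-0.15)), 3 * 6.72 / sqrt(n))
  expect_lt(abs(fit$sigma - 6.72), 3 * 6.72 / sqrt(2 * n) + 0.1)
  expect_gt(fit$R2, 0.9)
  expect_true(fit$better_than_constant)
})

test_that("fitted X is shift-equivariant and sigma/R2 shift-invariant", {
  centers <- seq(-9, 9, by = 3)
  set.seed(8)
  vals <- exp(-(centers - 1.2)^2 / (2 * 2.5^2)) + runif(7, 0, 0.05)
  d <- raw_dist(centers, vals / sum(vals))
  f0 <- fit_gaussian(d)
  for (delta in c(-6, 4.5)) {
    fd <- fit_gaussian(raw_dist(centers + delta, d$proportion))
    expect_equal(fd$X, f0$X + delta, tolerance = 1e-5)
    expect_equal(fd$sigma, f0$sigma, tolerance = 1e-6)
    expect_equal(fd$R2, f0$R2, tolerance = 1e-8)
  }
})

test_that("scaling proportions rescales the amplitude only", {
  centers <- seq(-12, 12, by = 3)
  vals <- exp(-(centers - 2)^2 / (2 * 3^2))
  f1 <- fit_gaussian(raw_dist(centers, vals))
  f3 <- fit_gaussian(raw_dist(centers, 3 * vals))
  expect_equal(f3$amplitude, 3 * f1$amplitude, tolerance = 1e-6)
  expect_equal(f3$X, f1$X, tolerance = 1e-6)
  expect_equal(f3$sigma, f1$sigma, tolerance = 1e-6)
})

test_that("fitted sigma tracks the generating sigma monotonically", {
  sigmas <- c(1.5, 3, 5, 8)
  fitted <- vapply(seq_along(sigmas), function(i) {
    tr <- pooled_design("auditory", 20, seed0 = 100 * i)
    p <- observer_profile(bias_a = 0, sigma_a = sigmas[i],
                          report_granularity = "continuous")
    rs <- simulate_unimodal(tr, p, seed = 1000 + i)
    fit_gaussian(error_distribution(rs, bin_width_deg = sigmas[i] / 2))$sigma
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("model methods behave like standard fitted-model accessors", {
  centers <- seq(-9, 9, by = 3)
  vals <- exp(-(centers - 1)^2 / (2 * 4^2))
  d <- binned_distribution(centers, vals / sum(vals))
  fit <- fit_gaussian(d)
  expect_named(coef(fit), c("X", "sigma", "amplitude"))
  expect_equal(fitted(fit) + residuals(fit), d$proportion)
  expect_equal(predict(fit, 1), fit$amplitude, tolerance = 1e-6)
  expect_equal(predict(fit), fitted(fit))
  expect_output(print(fit), "Gaussian psychometric fit")
  expect_output(print(summary(fit)), "residual SE")
  path <- tempfile(fileext = ".json")
  write_gaussian_fit(fit, path)
  rec <- jsonlite::read_json(path)
  expect_equal(rec$X, fit$X, tolerance = 1e-9)
})
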