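test_that("reliability-weighted fusion matches hand-evaluated values", {
  p <- human_params()
  # all cues agree
  p5 <- cima_params(sigma_a = 2, sigma_v = 1, mu_P = 5, sigma_P = 4)
  expect_equal(fuse_estimates(5, 5, p5), 5)
  # flat prior, printed human widths, -12 deg visual offset
  expect_equal(fuse_estimates(0, -12, p), -11.278, tolerance = 1e-3)
  # proper prior pulls the estimate toward 0
  p10 <- cima_params(sigma_a = 6.72, sigma_v = 1.7, mu_P = 0, sigma_P = 10)
  expect_equal(fuse_estimates(0, -12, p10), -10.980, tolerance = 1e-3)
  expect_error(fuse_estimates(NA, 0, p), "finite")
})

test_that("fusion is monotone, bounded by the cues, and symmetric in reliability", {
  p <- human_params()
  set.seed(1)
  for (i in 1:50) {
    xa <- runif(1, -30, 30); xv <- runif(1, -30, 30)
    f <- fuse_estimates(xa, xv, p)
    if (xa != xv) {
      expect_gt(f, min(xa, xv))
      expect_lt(f, max(xa, xv))
    }
    # monotone in each cue
    expect_gte(fuse_estimates(xa + 0.5, xv, p), f)
    expect_gte(fuse_estimates(xa, xv + 0.5, p), f)
    # swapping (X_a, sigma_a) <-> (X_v, sigma_v) leaves the estimate unchanged
    pswap <- cima_params(sigma_a = 1.7, sigma_v = 6.72)
    expect_equal(fuse_estimates(xv, xa, pswap), f)
  }
})

test_that("common-cause posterior obeys its limits and a quadrature oracle", {
  p <- cima_params(sigma_a = 2, sigma_v = 2, mu_P = 0, sigma_P = 5)
  expect_equal(common_cause_posterior(3, -7, p, p_common = 1), 1)
  expect_equal(common_cause_posterior(3, -7, p, p_common = 0), 0)
  post <- common_cause_posterior(0, 0, p, p_common = 0.5)
  expect_gt(post, 0.5)
  expect_lt(post, 1)
  # independent quadrature oracle for both marginal likelihoods
  like1 <- stats::integrate(function(s)
    dnorm(0, s, 2) * dnorm(0, s, 2) * dnorm(s, 0, 5),
    -Inf, Inf, rel.tol = 1e-10)$value
  like2 <- dnorm(0, 0, sqrt(4 + 25)) * dnorm(0, 0, sqrt(4 + 25))
  expect_equal(post, like1 / (like1 + like2), tolerance = 1e-6)
  # asymmetric cues against the same oracle
  p2 <- cima_params(sigma_a = 6.72, sigma_v = 1.7, mu_P = 0, sigma_P = 12)
  post2 <- common_cause_posterior(4, -8, p2, p_common = 0.3)
  l1 <- stats::integrate(function(s)
    dnorm(4, s, 6.72) * dnorm(-8, s, 1.7) * dnorm(s, 0, 12),
    -Inf, Inf, rel.tol = 1e-10)$value
  l2 <- dnorm(4, 0, sqrt(6.72^2 + 144)) * dnorm(-8, 0, sqrt(1.7^2 + 144))
  expect_equal(post2, 0.3 * l1 / (0.3 * l1 + 0.7 * l2), tolerance = 1e-6)
  expect_error(common_cause_posterior(0, 0, human_params(), p_common = 0.5),
               "proper prior")
})

test_that("Monte-Carlo response distributions behave in the degenerate and analytic limits", {
  # vanishing noise: all mass in the bin containing the -6 midpoint
  p_eps <- cima_params(sigma_a = 0.01, sigma_v = 0.01, n_samples = 500)
  d <- simulate_response_distribution(4.5, 4.5 - 12, p_eps, seed = 1)
  expect_equal(sum(d$proportion), 1, tolerance = 1e-12)
  expect_equal(d$bin_center_deg[which.max(d$proportion)], -6)
  expect_gt(max(d$proportion), 0.999)
  # printed human widths: fitted peak at the weighted fusion of the stimuli
  p <- human_params()
  S <- tone_positions()
  dl <- simulate_response_distribution(S, S - 12, p, seed = 2)
  expect_equal(sum(dl$proportion), 1, tolerance = 1e-12)
  fit <- fit_gaussian(dl)
  w_v <- (1 / 1.7^2) / (1 / 1.7^2 + 1 / 6.72^2)
  sem <- 1.7 / sqrt(length(S) * p$n_samples)
  expect_lt(abs(fit$X - w_v * -12), 3 * sem + 0.1)
})

test_that("empirical spread of fused estimates matches the analytic SD", {
  p <- human_params(n_samples = 20000L)
  d <- simulate_response_distribution(0, -12, p, seed = 5)
  m <- sum(d$bin_center_deg * d$proportion)
  v_binned <- sum((d$bin_center_deg - m)^2 * d$proportion)
  w_a <- (1 / 6.72^2) / (1 / 1.7^2 + 1 / 6.72^2)
  w_v <- 1 - w_a
  sd_analytic <- sqrt(w_a^2 * 6.72^2 + w_v^2 * 1.7^2)
  # Sheppard's correction removes the binning variance b^2/12
  sd_emp <- sqrt(v_binned - p$bin_width_deg^2 / 12)
  expect_lt(abs(sd_emp - sd_analytic), 0.05)
})

test_that("prior-width fitting recovers the generating prior on a grid", {
  base <- cima_params(sigma_a = 6.72, sigma_v = 1.7, mu_P = 0, sigma_P = 20,
                      n_samples = 20000L)
  observed <- simulate_response_distribution(0, -12, base, seed = 21)
  fit <- fit_sigma_P(observed, 0, -12,
                     cima_params(sigma_a = 6.72, sigma_v = 1.7, mu_P = 0,
                                 n_samples = 20000L),
                     grid = c(5, 20, 80), seed = 22)
  expect_equal(fit$sigma_P, 20)
  # flat-prior data prefer weak priors over strong ones
  flat_obs <- simulate_response_distribution(0, -12, human_params(20000L),
                                             seed = 23)
  fit2 <- fit_sigma_P(flat_obs, 0, -12,
                      cima_params(sigma_a = 6.72, sigma_v = 1.7, mu_P = 0,
                                  n_samples = 20000L),
                      grid = c(10, 100, Inf), seed = 24)
  expect_true(fit2$sigma_P %in% c(100, Inf))
  expect_lt(fit2$grid_nrmse["100"], fit2$grid_nrmse["10"])
  # single-element grid returns that element
  fit3 <- fit_sigma_P(observed, 0, -12, base, grid = 7, seed = 25)
  expect_equal(fit3$sigma_P, 7)
  expect_error(fit_sigma_P(observed, 0, -12, base, grid = numeric(0)), "grid")
})

test_that("Monte-Carlo simulation is seed-deterministic", {
  p <- human_params(2000L)
  expect_identical(simulate_response_distribution(4.5, -7.5, p, seed = 3),
                   simulate_response_distribution(4.5, -7.5, p, seed = 3))
})

test_that("parameter constructor rejects invalid settings", {
  expect_error(cima_params(sigma_a = 0, sigma_v = 1), "sigma_a")
  expect_error(cima_params(sigma_a = 1, sigma_v = 1, sigma_P = -3), "sigma_P")
  expect_error(cima_params(sigma_a = 1, sigma_v = 1, n_samples = 0), "n_samples")
  expect_true(cima_params(sigma_a = 1, sigma_v = 1)$flat_prior)
})
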