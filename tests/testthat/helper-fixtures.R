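# Shared fixtures: printed human unimodal fits and the standard task layout.

human_params <- function(n_samples = 10000L, sigma_P = Inf) {
  cima_params(sigma_a = 6.72, sigma_v = 1.7, mu_P = 0, sigma_P = sigma_P,
              n_samples = n_samples, bin_width_deg = 3)
}

tone_positions <- function() c(-22.5, -13.5, -4.5, 4.5, 13.5, 22.5)

# Two size-8 samples constructed so the first group wins exactly 25 of the
# 64 pairwise comparisons (U = 25), no ties.
u25_samples <- function() {
  list(x = c(45, 44, 43, 42, 35, 34, 25, 15),
       y = c(10, 20, 30, 40, 50, 60, 70, 80))
}

# Pool n_designs independent passes of a task design into one trial table.
pooled_design <- function(task, n_designs, seed0 = 1L) {
  do.call(rbind, lapply(seq_len(n_designs),
                        function(i) make_design(task, seed = seed0 + i)))
}

# Unnormalized binned-distribution stand-in for probing the fitter directly.
raw_dist <- function(centers, values) {
  out <- data.frame(bin_center_deg = centers, proportion = values)
  attr(out, "bin_width_deg") <- if (length(centers) > 1) diff(centers)[1] else NA
  class(out) <- c("binned_distribution", "data.frame")
  out
}
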