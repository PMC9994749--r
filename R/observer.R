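#' Synthetic observer profiles
#'
#' An observer profile describes a Gaussian response model per modality: the
#' reported position of a unimodal stimulus is the true position plus a
#' constant bias plus zero-mean Gaussian noise, with visual noise typically
#' much smaller than auditory noise. Two packaged profiles reproduce the
#' unimodal localization fits of the averaged human observer
#' (bias_v = 0.21 deg, sigma_v = 1.7 deg; bias_a = -0.15 deg,
#' sigma_a = 6.72 deg) and of the trained localization architecture
#' (bias_v = 0, sigma_v = 0.52 deg; bias_a = -1.44 deg, sigma_a = 5.52 deg).
#'
#' @param bias_v,bias_a Constant report bias per modality, degrees.
#' @param sigma_v,sigma_a Response noise SD per modality, degrees (> 0).
#' @param report_granularity `"nearest_module"` (responses are clicks on
#'   array modules, the default) or `"continuous"`.
#' @param name Optional profile label.
#' @return An object of class `observer_profile`.
#' @examples
#' observer_profile("human")
#' observer_profile("architecture")$sigma_v
#' @export
observer_profile <- function(name = NULL, bias_v = 0, sigma_v = 1,
                             bias_a = 0, sigma_a = 5,
                             report_granularity = c("nearest_module", "continuous")) {
  granularity_given <- !missing(report_granularity)
  report_granularity <- match.arg(report_granularity)
  if (!is.null(name) && name %in% c("human", "architecture")) {
    if (name == "human") {
      bias_v <- 0.21; sigma_v <- 1.7; bias_a <- -0.15; sigma_a <- 6.72
    } else {
      bias_v <- 0; sigma_v <- 0.52; bias_a <- -1.44; sigma_a <- 5.52
      # the architecture decodes continuous heatmap coordinates, not clicks
      if (!granularity_given) report_granularity <- "continuous"
    }
    # packaged profiles are "human-like": vision must be the reliable modality
    stopifnot(sigma_v < sigma_a)
  }
  if (!is.finite(sigma_v) || sigma_v <= 0) stop("`sigma_v` must be > 0")
  if (!is.finite(sigma_a) || sigma_a <= 0) stop("`sigma_a` must be > 0")
  structure(
    list(name = if (is.null(name)) "custom" else name,
         bias_v = bias_v, sigma_v = sigma_v,
         bias_a = bias_a, sigma_a = sigma_a,
         report_granularity = report_granularity),
    class = "observer_profile")
}

#' @export
print.observer_profile <- function(x, ...) {
  cat(sprintf("Observer profile '%s': visual N(%+.2f, %.2f), auditory N(%+.2f, %.2f) deg, reports %s\n",
              x$name, x$bias_v, x$sigma_v, x$bias_a, x$sigma_a,
              x$report_granularity))
  invisible(x)
}

# Snap reported positions per the profile's granularity.
apply_granularity <- function(reported, profile, geometry) {
  if (profile$report_granularity == "nearest_module")
    snap_to_module(reported, geometry)
  else reported
}

#' Simulate unimodal localization responses
#'
#' For each trial of a single-modality design, the reported position is the
#' true position plus the modality's bias plus Gaussian noise of the
#' modality's SD, optionally snapped to the nearest module (the default —
#' observers responded by clicking array modules).
#'
#' @param trials A `trial_table` whose rows are all auditory or all visual.
#' @param profile An [observer_profile()].
#' @param seed Integer seed.
#' @param geometry An [array_geometry()] (used for module snapping).
#' @return A `response_set`: the trial table plus `reported_deg` and
#'   `error_deg` (reported minus true position).
#' @examples
#' tr <- make_design("auditory", seed = 1)
#' head(simulate_unimodal(tr, observer_profile("human"), seed = 2))
#' @export
simulate_unimodal <- function(trials, profile, seed = 1L,
                              geometry = array_geometry()) {
  validate_trial_table(trials)
  tasks <- unique(trials$task)
  if (length(tasks) != 1L || !tasks %in% c("auditory", "visual"))
    stop("`trials` must be all-auditory or all-visual")
  truth <- if (tasks == "auditory") trials$S_a_deg else trials$S_v_deg
  bias <- if (tasks == "auditory") profile$bias_a else profile$bias_v
  sigma <- if (tasks == "auditory") profile$sigma_a else profile$sigma_v
  reported <- with_seed(seed, truth + bias + stats::rnorm(length(truth), 0, sigma))
  reported <- apply_granularity(reported, profile, geometry)
  out <- trials
  out$reported_deg <- reported
  out$error_deg <- reported - truth
  class(out) <- c("response_set", "data.frame")
  out
}

#' Simulate audiovisual localization responses by reliability-weighted fusion
#'
#' The common-cause generative process assumed by the causal-inference
#' observer: on each trial the observer draws noisy internal representations
#' `X_a ~ N(S_a + bias_a, sigma_a)` and `X_v ~ N(S_v + bias_v, sigma_v)` and
#' reports their reliability-weighted fusion with the spatial prior (see
#' [fuse_estimates()]). The report is interpreted as the tone's apparent
#' position, so `error_deg` is reported minus `S_a_deg` — the ventriloquist
#' shift toward the flash appears directly in the error distribution.
#'
#' @param trials An audiovisual `trial_table`.
#' @param profile An [observer_profile()].
#' @param prior List with `mu_P` (degrees) and `sigma_P` (degrees > 0, or
#'   `Inf` for a flat prior); default flat.
#' @param seed Integer seed.
#' @param geometry An [array_geometry()].
#' @return A `response_set` with `reported_deg` and `error_deg`
#'   (reported minus `S_a_deg`).
#' @export
simulate_audiovisual <- function(trials, profile,
                                 prior = list(mu_P = 0, sigma_P = Inf),
                                 seed = 1L, geometry = array_geometry()) {
  validate_trial_table(trials)
  if (!all(trials$task == "audiovisual"))
    stop("`trials` must be all-audiovisual")
  if (!is.finite(prior$sigma_P) && !is.infinite(prior$sigma_P))
    stop("`sigma_P` must be positive or Inf (flat prior)")
  if (prior$sigma_P <= 0) stop("`sigma_P` must be > 0 (use Inf for a flat prior)")
  params <- cima_params(sigma_a = profile$sigma_a, sigma_v = profile$sigma_v,
                        mu_P = prior$mu_P, sigma_P = prior$sigma_P)
  n <- nrow(trials)
  reported <- with_seed(seed, {
    X_a <- stats::rnorm(n, trials$S_a_deg + profile$bias_a, profile$sigma_a)
    X_v <- stats::rnorm(n, trials$S_v_deg + profile$bias_v, profile$sigma_v)
    fuse_estimates(X_a, X_v, params)
  })
  reported <- apply_granularity(reported, profile, geometry)
  out <- trials
  out$reported_deg <- reported
  out$error_deg <- reported - trials$S_a_deg
  class(out) <- c("response_set", "data.frame")
  out
}

#' Write / read a response set as CSV
#'
#' @param responses A `response_set`.
#' @param path File path.
#' @export
write_response_set <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_set
#' @export
read_response_set <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("S_a_deg", "S_v_deg"))  # all-NA columns come back logical
    if (col %in% names(out)) out[[col]] <- as.numeric(out[[col]])
  class(out) <- c("response_set", "data.frame")
  out
}
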