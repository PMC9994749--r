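#' Synthesize a two-microphone audio scene
#'
#' Generates the synthetic stand-in for a recorded localization trial: a
#' train of 2 kHz sine pulses emitted from a given azimuth and picked up by
#' two microphones 40 cm apart, under a far-field plane-wave model. The
#' inter-channel delay is \eqn{\tau = d \sin(\theta) / c}; channel 1 is the
#' left microphone and lags channel 2 for sources on the right
#' (positive azimuth). Fractional delays are exact (the pulse train is
#' evaluated in continuous time at each channel's shifted time axis), and
#' independent white Gaussian noise is added per channel.
#'
#' The default stimulus is five 60-ms pulses with 5-ms raised-cosine ramps
#' spread over the 500-ms trace; the pulse envelope gives the tone the
#' spectral spread that makes two-microphone direction finding with a
#' narrowband carrier well-posed.
#'
#' @param azimuth_deg Source azimuth, degrees, |azimuth| < 90 (0 =
#'   broadside, negative = left).
#' @param fs Sampling frequency, Hz (default 12288).
#' @param duration Trace duration, seconds (default 0.5).
#' @param freq Carrier frequency, Hz (default 2000).
#' @param mic_spacing Microphone spacing, meters (default 0.40).
#' @param speed_of_sound Meters per second (default 343).
#' @param noise_level White-noise SD relative to unit pulse amplitude.
#' @param n_pulses,pulse_dur,ramp_dur Pulse-train shape (count, seconds).
#' @param seed Integer seed for the noise.
#' @return An `audio_scene`: list with `waveforms` (matrix, samples x 2),
#'   `fs`, `duration`, `source_azimuth_deg`, `mic_spacing_m`,
#'   `speed_of_sound`, `delay_s` (channel-1 lag relative to channel 2).
#' @examples
#' sc <- synth_audio_scene(12)
#' sc$delay_s * sc$fs   # about 2.98 samples of inter-channel delay
#' @export
synth_audio_scene <- function(azimuth_deg, fs = 12288, duration = 0.5,
                              freq = 2000, mic_spacing = 0.40,
                              speed_of_sound = 343, noise_level = 0,
                              n_pulses = 5, pulse_dur = 0.06,
                              ramp_dur = 0.005, seed = 1L) {
  if (!is.finite(azimuth_deg) || abs(azimuth_deg) >= 90)
    stop("`azimuth_deg` must satisfy |azimuth| < 90")
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  starts <- (seq_len(n_pulses) - 1) * duration / n_pulses
  pulse_train <- function(tt) {
    env <- numeric(length(tt))
    for (s in starts) {
      u <- tt - s
      ramp_in <- u >= 0 & u < ramp_dur
      flat <- u >= ramp_dur & u < pulse_dur - ramp_dur
      ramp_out <- u >= pulse_dur - ramp_dur & u < pulse_dur
      env[ramp_in] <- env[ramp_in] + 0.5 * (1 - cos(pi * u[ramp_in] / ramp_dur))
      env[flat] <- env[flat] + 1
      env[ramp_out] <- env[ramp_out] +
        0.5 * (1 - cos(pi * (pulse_dur - u[ramp_out]) / ramp_dur))
    }
    env * sin(2 * pi * freq * tt)
  }
  tau <- mic_spacing * sin(azimuth_deg * pi / 180) / speed_of_sound
  # mic 1 (left) at -d/2, mic 2 (right) at +d/2: right mic hears a
  # right-hand source earlier, so channel 1 is delayed by tau relative to 2
  ch1 <- pulse_train(t - tau / 2)
  ch2 <- pulse_train(t + tau / 2)
  if (noise_level > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(2 * n, 0, noise_level), ncol = 2))
    ch1 <- ch1 + noise[, 1]
    ch2 <- ch2 + noise[, 2]
  }
  structure(
    list(waveforms = cbind(ch1, ch2), fs = fs, duration = duration,
         source_azimuth_deg = azimuth_deg, mic_spacing_m = mic_spacing,
         speed_of_sound = speed_of_sound, delay_s = tau),
    class = "audio_scene")
}

#' @export
print.audio_scene <- function(x, ...) {
  cat(sprintf("Audio scene: %d samples x 2 ch at %g Hz, source %+g deg, mic spacing %g m\n",
              nrow(x$waveforms), x$fs, x$source_azimuth_deg, x$mic_spacing_m))
  invisible(x)
}

#' Delay-and-sum beamforming features with mel-cepstral compression
#'
#' Steers the two-microphone pair over a grid of candidate azimuths
#' (by default the 24 module directions of the stimulus array) in the
#' frequency domain: each channel's spectrum is phase-advanced by the delay
#' expected from that direction and the aligned channels are summed, giving
#' one energy per direction. Signals from the matching direction add
#' coherently, so the energy profile peaks at the source azimuth. The
#' beamformed signal of the best direction is additionally compressed to
#' mel-frequency cepstral coefficients (13 coefficients, 25-ms Hamming
#' windows, 10-ms hop, 26-filter mel bank to fs/2).
#'
#' @param scene An [audio_scene()].
#' @param directions_deg Candidate azimuths, degrees (>= 2); default the
#'   module centers of [array_geometry()].
#' @param geometry Array geometry used for the default direction grid.
#' @return A `beamform_features` list: `directions_deg`, `energy` (one per
#'   direction), `best_direction_deg`, `mfcc` (frames x 13 matrix),
#'   `mfcc_mean` (length-13 summary), `silent` (TRUE when the scene has no
#'   energy, in which case energies are all zero).
#' @export
beamform_features <- function(scene, directions_deg = NULL,
                              geometry = array_geometry()) {
  stopifnot(inherits(scene, "audio_scene"))
  if (is.null(directions_deg)) directions_deg <- module_centers_deg(geometry)
  if (length(directions_deg) < 2L) stop("need at least 2 candidate directions")
  w <- scene$waveforms
  n <- nrow(w)
  if (all(w == 0)) {
    return(structure(
      list(directions_deg = directions_deg,
           energy = numeric(length(directions_deg)),
           best_direction_deg = NA_real_,
           mfcc = NULL, mfcc_mean = rep(NA_real_, 13), silent = TRUE),
      class = "beamform_features"))
  }
  X1 <- stats::fft(w[, 1])
  X2 <- stats::fft(w[, 2])
  fbins <- c(0:(floor(n / 2)), -((n - floor(n / 2) - 1):1)) * scene$fs / n
  half <- mic_half_delays(directions_deg, scene)  # per-channel delays
  energy <- vapply(seq_along(directions_deg), function(k) {
    # advance each channel by its expected delay so the source aligns
    Y <- X1 * exp(2i * pi * fbins * half$ch1[k]) +
      X2 * exp(2i * pi * fbins * half$ch2[k])
    sum(Mod(Y)^2) / n
  }, numeric(1))
  best <- which.max(energy)
  Yb <- X1 * exp(2i * pi * fbins * half$ch1[best]) +
    X2 * exp(2i * pi * fbins * half$ch2[best])
  yb <- Re(stats::fft(Yb, inverse = TRUE)) / n
  mf <- mfcc(yb, scene$fs)
  structure(
    list(directions_deg = directions_deg, energy = energy,
         best_direction_deg = directions_deg[best],
         mfcc = mf, mfcc_mean = colMeans(mf), silent = FALSE),
    class = "beamform_features")
}

# Per-channel steering delays (seconds) toward each candidate azimuth,
# matching the mic layout of synth_audio_scene.
mic_half_delays <- function(directions_deg, scene) {
  tau <- scene$mic_spacing_m * sin(directions_deg * pi / 180) /
    scene$speed_of_sound
  list(ch1 = tau / 2, ch2 = -tau / 2)
}

#' @export
print.beamform_features <- function(x, ...) {
  if (x$silent) cat("Beamforming features: silent scene (zero energy)\n")
  else cat(sprintf("Beamforming features: %d directions, peak at %+g deg\n",
                   length(x$directions_deg), x$best_direction_deg))
  invisible(x)
}

# Mel-frequency cepstral coefficients: framed power spectrum -> triangular
# mel filter bank -> log -> DCT-II. Returns frames x n_cep.
mfcc <- function(x, fs, n_cep = 13, n_filters = 26,
                 window_s = 0.025, hop_s = 0.010, n_fft = 512) {
  win_len <- round(window_s * fs)
  hop <- round(hop_s * fs)
  if (length(x) < win_len) stop("signal shorter than one analysis window")
  n_frames <- 1 + floor((length(x) - win_len) / hop)
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_len(win_len) - 1) / (win_len - 1))
  fb <- mel_filterbank(fs, n_fft, n_filters)
  n_bins <- n_fft / 2 + 1
  cep <- matrix(0, n_frames, n_cep)
  dct <- dct_matrix(n_cep, n_filters)
  for (i in seq_len(n_frames)) {
    frame <- x[(i - 1) * hop + seq_len(win_len)] * ham
    spec <- stats::fft(c(frame, numeric(n_fft - win_len)))
    pow <- Mod(spec[seq_len(n_bins)])^2 / n_fft
    fe <- as.numeric(fb %*% pow)
    cep[i, ] <- as.numeric(dct %*% log(pmax(fe, .Machine$double.eps)))
  }
  cep
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular filters equally spaced on the mel scale from 0 to fs/2.
mel_filterbank <- function(fs, n_fft, n_filters) {
  n_bins <- n_fft / 2 + 1
  freqs <- (seq_len(n_bins) - 1) * fs / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(fs / 2),
                         length.out = n_filters + 2))
  fb <- matrix(0, n_filters, n_bins)
  for (j in seq_len(n_filters)) {
    lo <- edges[j]; mid <- edges[j + 1]; hi <- edges[j + 2]
    up <- freqs >= lo & freqs <= mid
    down <- freqs > mid & freqs <= hi
    fb[j, up] <- (freqs[up] - lo) / max(mid - lo, .Machine$double.eps)
    fb[j, down] <- (hi - freqs[down]) / max(hi - mid, .Machine$double.eps)
  }
  fb
}

# Orthonormal DCT-II, first n_cep rows.
dct_matrix <- function(n_cep, n_in) {
  m <- outer(0:(n_cep - 1), 0:(n_in - 1),
             function(k, n) cos(pi * (n + 0.5) * k / n_in)) * sqrt(2 / n_in)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

#' Rasterize direction energies into a 2D feature map
#'
#' Interpolates the per-direction beamforming energies across the raster
#' width and replicates the resulting row along the vertical axis — the
#' stimulus array has a fixed vertical position, so the audio carries no
#' vertical information and the horizontal profile is simply copied to every
#' row to obtain a 2D localization-map input.
#'
#' @param features A [beamform_features()] result.
#' @param height,width Output raster size (default 224 x 298).
#' @return A `height` x `width` numeric matrix.
#' @export
rasterize_audio_features <- function(features, height = 224, width = 298) {
  stopifnot(inherits(features, "beamform_features"))
  dirs <- features$directions_deg
  cols <- seq(min(dirs), max(dirs), length.out = width)
  row <- stats::approx(dirs, features$energy, xout = cols, rule = 2)$y
  matrix(rep(row, each = height), nrow = height)
}
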