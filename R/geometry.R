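#' Stimulus array geometry
#'
#' Describes the linear stimulus array used in the localization tasks: a row
#' of identical modules (each able to emit a flash or a tone) centered on the
#' observer's midline. The default is the 24-module array spanning +/- 36
#' degrees of visual angle at a viewing distance of 180 cm, giving an angular
#' pitch of 3 degrees per module. 0 degrees is the array center; negative
#' angles are leftward.
#'
#' @param n_modules Number of modules in the array (>= 2).
#' @param half_span_deg Half the angular span of the array, in degrees of
#'   visual angle (> 0).
#' @param viewing_distance_cm Viewing distance in centimeters (> 0).
#' @return An object of class `array_geometry`: a list with the three fields
#'   above plus `pitch_deg`, the angular pitch of one module.
#' @examples
#' geom <- array_geometry()
#' geom$pitch_deg            # 3 degrees per module
#' modules_to_degrees(4, geom)  # 12 degrees
#' @export
array_geometry <- function(n_modules = 24L, half_span_deg = 36,
                           viewing_distance_cm = 180) {
  n_modules <- as.integer(n_modules)
  if (is.na(n_modules) || n_modules < 2L)
    stop("`n_modules` must be an integer >= 2")
  if (!is.finite(half_span_deg) || half_span_deg <= 0)
    stop("`half_span_deg` must be > 0")
  if (!is.finite(viewing_distance_cm) || viewing_distance_cm <= 0)
    stop("`viewing_distance_cm` must be > 0")
  structure(
    list(n_modules = n_modules,
         half_span_deg = half_span_deg,
         viewing_distance_cm = viewing_distance_cm,
         pitch_deg = 2 * half_span_deg / n_modules),
    class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("Linear stimulus array: %d modules, +/-%g deg at %g cm (pitch %g deg/module)\n",
              x$n_modules, x$half_span_deg, x$viewing_distance_cm, x$pitch_deg))
  invisible(x)
}

#' Convert module shifts to degrees of visual angle
#'
#' A displacement expressed as a signed number of modules is converted to
#' degrees using the array's angular pitch. The sign is preserved (negative =
#' leftward). The inverse conversion is [degrees_to_modules()].
#'
#' @param shift Signed module count (may be fractional).
#' @param geometry An [array_geometry()].
#' @return Degrees of visual angle.
#' @examples
#' modules_to_degrees(c(-2, -1, 0, 1, 2), array_geometry())
#' @export
modules_to_degrees <- function(shift, geometry = array_geometry()) {
  stopifnot(inherits(geometry, "array_geometry"))
  shift * geometry$pitch_deg
}

#' @rdname modules_to_degrees
#' @param degrees Degrees of visual angle.
#' @export
degrees_to_modules <- function(degrees, geometry = array_geometry()) {
  stopifnot(inherits(geometry, "array_geometry"))
  degrees / geometry$pitch_deg
}

#' Module center positions
#'
#' Angular position of each module's center. Modules are numbered 1 (leftmost)
#' to `n_modules` (rightmost); centers sit at half-pitch offsets so the array
#' is symmetric about 0 degrees (for the default array: -34.5, -31.5, ...,
#' +34.5).
#'
#' @param geometry An [array_geometry()].
#' @return Numeric vector of length `n_modules`, in degrees.
#' @export
module_centers_deg <- function(geometry = array_geometry()) {
  stopifnot(inherits(geometry, "array_geometry"))
  p <- geometry$pitch_deg
  (seq_len(geometry$n_modules) - (geometry$n_modules + 1) / 2) * p
}

#' Snap positions to the nearest module center
#'
#' @param degrees Positions in degrees.
#' @param geometry An [array_geometry()].
#' @return Positions snapped to the nearest module center, in degrees.
#' @export
snap_to_module <- function(degrees, geometry = array_geometry()) {
  centers <- module_centers_deg(geometry)
  centers[vapply(degrees, function(d) which.min(abs(centers - d)), integer(1))]
}

# Stimulus position sets for the three localization tasks (degrees).
auditory_positions <- function() c(-22.5, -13.5, -4.5, 4.5, 13.5, 22.5)
visual_positions <- function()
  sort(c(-1, 1) %o% c(1.5, 7.5, 10.5, 16.5, 25.5, 34.5))

#' Generate a localization-task trial table
#'
#' Builds the trial list for one of the three psychophysical tasks run on the
#' array, in a pseudo-random (seeded uniform shuffle) order:
#'
#' * `"auditory"`: tones at +/-4.5, +/-13.5, +/-22.5 degrees, 10 repetitions
#'   each (60 trials).
#' * `"visual"`: flashes at +/-1.5, +/-7.5, +/-10.5, +/-16.5, +/-25.5,
#'   +/-34.5 degrees, 5 repetitions each (60 trials).
#' * `"audiovisual"`: a tone at each auditory position paired with a
#'   synchronous flash displaced `displacement_deg` to the left or to the
#'   right of it, 5 repetitions per pairing (60 trials). With the default
#'   12-degree displacement every flash position coincides with a
#'   visual-task position, so the bimodal stimuli reuse calibrated unimodal
#'   locations.
#'
#' @param task One of `"auditory"`, `"visual"`, `"audiovisual"`.
#' @param geometry An [array_geometry()].
#' @param seed Integer seed controlling the trial order.
#' @param displacement_deg Audiovisual flash offset from the tone, degrees.
#' @return A `trial_table`: a data.frame with columns `task`, `S_a_deg`
#'   (tone position; NA for visual trials), `S_v_deg` (flash position; NA for
#'   auditory trials) and `repetition`.
#' @examples
#' head(make_design("audiovisual", seed = 1))
#' @export
make_design <- function(task = c("auditory", "visual", "audiovisual"),
                        geometry = array_geometry(), seed = 1L,
                        displacement_deg = 12) {
  task <- match.arg(task)
  if (task == "auditory") {
    pos <- auditory_positions()
    grid <- expand.grid(S_a_deg = pos, repetition = 1:10)
    grid$S_v_deg <- NA_real_
  } else if (task == "visual") {
    pos <- visual_positions()
    grid <- expand.grid(S_v_deg = pos, repetition = 1:5)
    grid$S_a_deg <- NA_real_
  } else {
    grid <- expand.grid(S_a_deg = auditory_positions(),
                        offset = c(-displacement_deg, displacement_deg),
                        repetition = 1:5)
    grid$S_v_deg <- grid$S_a_deg + grid$offset
    grid$offset <- NULL
  }
  grid$task <- task
  grid <- grid[, c("task", "S_a_deg", "S_v_deg", "repetition")]
  ord <- with_seed(seed, sample.int(nrow(grid)))
  out <- grid[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Validate a trial table
#'
#' Checks the structural invariants of a trial table: unimodal rows carry only
#' the matching stimulus column, audiovisual rows carry both with a constant
#' absolute displacement.
#'
#' @param trials A `trial_table`.
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_trial_table <- function(trials) {
  stopifnot(is.data.frame(trials))
  need <- c("task", "S_a_deg", "S_v_deg", "repetition")
  if (!all(need %in% names(trials)))
    stop("trial table must have columns ", paste(need, collapse = ", "))
  aud <- trials$task == "auditory"
  vis <- trials$task == "visual"
  av <- trials$task == "audiovisual"
  if (any(aud & (is.na(trials$S_a_deg) | !is.na(trials$S_v_deg))))
    stop("auditory rows must have S_a_deg only")
  if (any(vis & (is.na(trials$S_v_deg) | !is.na(trials$S_a_deg))))
    stop("visual rows must have S_v_deg only")
  if (any(av & (is.na(trials$S_a_deg) | is.na(trials$S_v_deg))))
    stop("audiovisual rows must have both S_a_deg and S_v_deg")
  if (any(av)) {
    d <- abs(trials$S_v_deg[av] - trials$S_a_deg[av])
    if (length(unique(round(d, 9))) != 1L)
      stop("audiovisual displacement must be constant across rows")
  }
  invisible(TRUE)
}

#' Write / read a trial table as CSV
#'
#' @param trials A `trial_table`.
#' @param path File path.
#' @return `write_trial_table` returns `path` invisibly; `read_trial_table`
#'   returns the `trial_table`.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("S_a_deg", "S_v_deg"))  # all-NA columns come back logical
    if (col %in% names(out)) out[[col]] <- as.numeric(out[[col]])
  class(out) <- c("trial_table", "data.frame")
  validate_trial_table(out)
  out
}
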