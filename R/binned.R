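#' Binned response distribution
#'
#' A binned relative-frequency distribution of localization responses (or
#' localization errors). Bin centers fall on integer multiples of the bin
#' width, matching the angular pitch of the stimulus array when the default
#' 3-degree bins are used; a value lying exactly on a bin edge is counted in
#' the bin to its right.
#'
#' @param bin_centers Numeric vector of equally spaced bin centers (degrees).
#' @param proportions Non-negative relative frequencies, summing to 1.
#' @param bin_width_deg Bin width; inferred from the center spacing when
#'   omitted (required to be given for a single-bin distribution to be
#'   alignable with others).
#' @return A `binned_distribution`: data.frame with columns `bin_center_deg`
#'   and `proportion`, with attribute `bin_width_deg`.
#' @export
binned_distribution <- function(bin_centers, proportions, bin_width_deg = NULL) {
  stopifnot(length(bin_centers) == length(proportions), length(bin_centers) >= 1L)
  if (any(!is.finite(proportions)) || any(proportions < -1e-12))
    stop("proportions must be finite and non-negative")
  proportions <- pmax(proportions, 0)
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1 (got ", format(sum(proportions)), ")")
  if (length(bin_centers) > 1L) {
    d <- diff(bin_centers)
    if (any(abs(d - d[1]) > 1e-9)) stop("bin centers must be equally spaced")
    bw <- d[1]
    if (!is.null(bin_width_deg) && abs(bin_width_deg - bw) > 1e-9)
      stop("`bin_width_deg` contradicts the bin-center spacing")
  } else bw <- if (is.null(bin_width_deg)) NA_real_ else bin_width_deg
  out <- data.frame(bin_center_deg = bin_centers, proportion = proportions)
  attr(out, "bin_width_deg") <- bw
  class(out) <- c("binned_distribution", "data.frame")
  out
}

#' Bin a set of values into a relative-frequency distribution
#'
#' Values are assigned to bins whose centers are integer multiples of
#' `bin_width_deg`; a value on an edge goes to the right bin. Interior empty
#' bins are kept (proportion 0) so the support is contiguous.
#'
#' @param x Numeric values (degrees).
#' @param bin_width_deg Bin width in degrees (> 0), default 3.
#' @return A [binned_distribution()].
#' @examples
#' bin_values(c(-3, 0, 0, 3), bin_width_deg = 3)
#' @export
bin_values <- function(x, bin_width_deg = 3) {
  if (length(x) == 0L) stop("no values to bin")
  if (any(!is.finite(x))) stop("values must be finite")
  if (!is.finite(bin_width_deg) || bin_width_deg <= 0)
    stop("`bin_width_deg` must be > 0")
  # edge at center + bw/2 belongs to the right bin: floor((x + bw/2)/bw)
  idx <- floor((x + bin_width_deg / 2) / bin_width_deg)
  rng <- seq(min(idx), max(idx))
  counts <- tabulate(idx - min(idx) + 1L, nbins = length(rng))
  binned_distribution(rng * bin_width_deg, counts / length(x), bin_width_deg)
}

#' @export
print.binned_distribution <- function(x, ...) {
  cat(sprintf("Binned response distribution: %d bins of %s deg, support [%g, %g]\n",
              nrow(x), format(attr(x, "bin_width_deg")),
              min(x$bin_center_deg), max(x$bin_center_deg)))
  print.data.frame(x, ...)
  invisible(x)
}

# Align two binned distributions onto the union of their bin grids, padding
# with zeros. Grids must share bin width and phase.
align_bins <- function(a, b) {
  stopifnot(inherits(a, "binned_distribution"), inherits(b, "binned_distribution"))
  bw <- attr(a, "bin_width_deg")
  bwb <- attr(b, "bin_width_deg")
  if (is.na(bw)) bw <- bwb
  if (is.na(bw)) stop("bin width unknown for both distributions")
  if (!is.na(bwb) && !isTRUE(all.equal(bw, bwb)))
    stop("bin widths differ")
  phase <- a$bin_center_deg[1] %% bw
  if (abs((b$bin_center_deg[1] %% bw) - phase) > 1e-9 &&
      abs((b$bin_center_deg[1] %% bw) - phase - bw) > 1e-9)
    stop("bin grids are not in phase")
  centers <- seq(min(a$bin_center_deg[1], b$bin_center_deg[1]),
                 max(a$bin_center_deg[nrow(a)], b$bin_center_deg[nrow(b)]),
                 by = bw)
  pad <- function(d) {
    p <- numeric(length(centers))
    p[match(round(d$bin_center_deg / bw), round(centers / bw))] <- d$proportion
    p
  }
  list(bin_centers = centers, a = pad(a), b = pad(b))
}

#' Write / read a binned distribution as CSV
#'
#' @param dist A [binned_distribution()].
#' @param path File path.
#' @export
write_binned_distribution <- function(dist, path) {
  utils::write.csv(as.data.frame(dist), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binned_distribution
#' @export
read_binned_distribution <- function(path) {
  d <- utils::read.csv(path)
  binned_distribution(d$bin_center_deg, d$proportion)
}
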