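#' Module annotations on the localization raster
#'
#' Rectangular pixel masks marking each array module on the fixed
#' 224 x 298 localization raster. Module boxes tile the raster width in
#' array order (module 1 leftmost) and sit in a horizontal band centered
#' vertically — the array's vertical position is fixed. Boxes are half-open
#' `(x0, y0, x1, y1)` in 0-based pixel coordinates; pixel `i` (1-based R
#' index) covers the interval `[i-1, i)` with center `i - 0.5`.
#'
#' @param geometry An [array_geometry()].
#' @param width,height Raster size in pixels (default 298 x 224).
#' @param band_height Vertical extent of the module band, pixels.
#' @return A `module_annotations` data.frame with columns `module_id`,
#'   `x0`, `y0`, `x1`, `y1`.
#' @export
module_annotations <- function(geometry = array_geometry(),
                               width = 298, height = 224, band_height = 12) {
  n <- geometry$n_modules
  xb <- round(seq(0, width, length.out = n + 1))
  y0 <- round((height - band_height) / 2)
  out <- data.frame(module_id = seq_len(n),
                    x0 = xb[-(n + 1)], y0 = y0,
                    x1 = xb[-1], y1 = y0 + band_height)
  if (any(out$x1 <= out$x0)) stop("degenerate module rectangle")
  attr(out, "raster") <- c(height = height, width = width)
  class(out) <- c("module_annotations", "data.frame")
  out
}

rect_center <- function(box) c(x = (box$x0 + box$x1) / 2, y = (box$y0 + box$y1) / 2)

#' Ground-truth Gaussian localization heatmap
#'
#' Builds the ground-truth target for heatmap-based localization: an
#' isotropic 2D Gaussian centered on the annotated module rectangle, whose
#' full width at half maximum equals the rectangle's larger dimension (the
#' "diameter" of the blob), i.e. `sigma = max(width, height) / 2.355`. The
#' map peaks at 1 on the pixel nearest the rectangle center.
#'
#' @param annotation A single-row slice of [module_annotations()] (or any
#'   list with `x0`, `y0`, `x1`, `y1`).
#' @param height,width Raster size in pixels (default 224 x 298).
#' @return A `height` x `width` matrix, class `heatmap_matrix`.
#' @export
make_gt_heatmap <- function(annotation, height = 224, width = 298) {
  box <- as.list(annotation)
  if (box$x1 <= box$x0 || box$y1 <= box$y0) stop("degenerate rectangle")
  if (box$x0 < 0 || box$y0 < 0 || box$x1 > width || box$y1 > height)
    stop("rectangle outside raster bounds")
  ctr <- rect_center(box)
  diameter <- max(box$x1 - box$x0, box$y1 - box$y0)
  sigma <- diameter / (2 * sqrt(2 * log(2)))  # FWHM convention
  px <- seq_len(width) - 0.5
  py <- seq_len(height) - 0.5
  g <- exp(-outer((py - ctr["y"])^2, (px - ctr["x"])^2, "+") / (2 * sigma^2))
  structure(g / max(g), class = c("heatmap_matrix", "matrix", "array"))
}

#' Soft-argmax decoding of a localization heatmap
#'
#' Differentiable coordinate decoding: the map is scaled by a weight that
#' sharpens the peak, passed through a softmax over all pixels, and the
#' probability-weighted mean pixel-center coordinate is returned. Larger
#' weights approach the hard argmax; a uniform map decodes to the image
#' center.
#'
#' @param map Numeric matrix (finite values).
#' @param weight Positive sharpening weight multiplying the map before the
#'   softmax (default 30).
#' @return Named vector `c(row, col)` in continuous pixel-center
#'   coordinates (pixel i has center i - 0.5).
#' @export
soft_argmax <- function(map, weight = 30) {
  if (!is.matrix(map) || any(!is.finite(map))) stop("`map` must be a finite matrix")
  if (!is.finite(weight) || weight <= 0) stop("`weight` must be > 0")
  z <- weight * map
  p <- exp(z - max(z))
  p <- p / sum(p)
  rows <- row(map) - 0.5
  cols <- col(map) - 0.5
  c(row = sum(p * rows), col = sum(p * cols))
}

# Softmax-normalize a map into a probability distribution over pixels.
softmax_map <- function(map) {
  p <- exp(map - max(map))
  p / sum(p)
}

#' Heatmap losses: Kullback-Leibler, map MSE, coordinate MSE
#'
#' The training losses of a heatmap-localization model. Both maps are
#' softmax-normalized into pixel probability distributions before the KL
#' divergence `KL(gt || pred)` is taken (so it is 0 iff the maps are equal
#' up to an additive constant, and strictly positive otherwise); the map MSE
#' is the mean squared pixel difference of the raw maps; the coordinate MSE
#' is the squared distance between the soft-argmax decodings.
#' `combined_map_loss` mixes KL and map MSE with the KL weighted more
#' heavily (`w_kl > w_mse` is enforced), which is what makes the combined
#' loss attain its strict minimum at `pred = gt`.
#'
#' @param pred,gt Numeric matrices of identical shape.
#' @param w_kl,w_mse Positive mixing weights, `w_kl > w_mse`.
#' @param weight Soft-argmax sharpening weight (coordinate loss only).
#' @return A non-negative scalar.
#' @export
kl_map_loss <- function(pred, gt) {
  check_same_shape(pred, gt)
  p <- softmax_map(gt)
  q <- softmax_map(pred)
  sum(p * (log(p) - log(q)))
}

#' @rdname kl_map_loss
#' @export
mse_map_loss <- function(pred, gt) {
  check_same_shape(pred, gt)
  mean((pred - gt)^2)
}

#' @rdname kl_map_loss
#' @export
mse_coord_loss <- function(pred, gt, weight = 30) {
  check_same_shape(pred, gt)
  sum((soft_argmax(pred, weight) - soft_argmax(gt, weight))^2)
}

#' @rdname kl_map_loss
#' @export
combined_map_loss <- function(pred, gt, w_kl = 1, w_mse = 0.1) {
  if (!(w_kl > w_mse) || w_mse < 0)
    stop("weights must satisfy w_kl > w_mse >= 0")
  w_kl * kl_map_loss(pred, gt) + w_mse * mse_map_loss(pred, gt)
}

check_same_shape <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || !identical(dim(a), dim(b)))
    stop("maps must be matrices of identical shape")
  invisible(TRUE)
}

#' Intersection over union of two pixel rectangles
#'
#' @param a,b Rectangles as lists/rows with half-open `x0`, `y0`, `x1`, `y1`.
#' @return IOU in \[0, 1\].
#' @examples
#' iou(list(x0 = 0, y0 = 0, x1 = 2, y1 = 2),
#'     list(x0 = 1, y0 = 0, x1 = 3, y1 = 2))  # 1/3
#' @export
iou <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  ix <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  iy <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- ix * iy
  union <- (a$x1 - a$x0) * (a$y1 - a$y0) + (b$x1 - b$x0) * (b$y1 - b$y0) - inter
  if (union <= 0) stop("degenerate rectangles")
  inter / union
}

# Bounding box (half-open, 0-based) of the connected region of
# above-threshold pixels containing the argmax; 4-connectivity flood fill.
predicted_box <- function(map, threshold_frac = 0.5) {
  mask <- map >= threshold_frac * max(map)
  start <- which(map == max(map), arr.ind = TRUE)[1, ]
  nr <- nrow(map); nc <- ncol(map)
  seen <- matrix(FALSE, nr, nc)
  queue <- matrix(start, ncol = 2)
  seen[start[1], start[2]] <- TRUE
  rows <- start[1]; cols <- start[2]
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- cur[1] + d[1]; cc <- cur[2] + d[2]
      if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
          !seen[r, cc] && mask[r, cc]) {
        seen[r, cc] <- TRUE
        queue <- rbind(queue, c(r, cc))
        rows <- c(rows, r); cols <- c(cols, cc)
      }
    }
  }
  list(x0 = min(cols) - 1, y0 = min(rows) - 1, x1 = max(cols), y1 = max(rows))
}

#' Assign a predicted heatmap to an array module
#'
#' Extracts a predicted region from the map — the connected set of pixels at
#' or above 50% of the maximum that contains the argmax, taken as its
#' bounding box — and returns the module whose annotation rectangle has the
#' highest intersection-over-union with it. Ties are broken toward the
#' module whose center is nearest the map's argmax.
#'
#' @param map Numeric matrix with at least one positive value.
#' @param annotations A [module_annotations()] table covering the array.
#' @param threshold_frac Region threshold as a fraction of the map maximum.
#' @return The winning `module_id` (integer).
#' @export
assign_module <- function(map, annotations, threshold_frac = 0.5) {
  stopifnot(inherits(annotations, "module_annotations"))
  if (!is.matrix(map) || all(map <= 0)) stop("map has no positive values")
  box <- predicted_box(map, threshold_frac)
  ious <- vapply(seq_len(nrow(annotations)),
                 function(i) iou(box, annotations[i, ]), numeric(1))
  best <- which(ious == max(ious))
  if (length(best) > 1L) {
    am <- which(map == max(map), arr.ind = TRUE)[1, ]
    cx <- am[2] - 0.5
    dist <- vapply(best, function(i) {
      abs((annotations$x0[i] + annotations$x1[i]) / 2 - cx)
    }, numeric(1))
    best <- best[which.min(dist)]
  }
  annotations$module_id[best]
}

#' Relative-frequency histogram of localization shifts
#'
#' Tabulates the signed shift (predicted minus true module) across trials
#' and normalizes by the trial count, giving the relative frequency of each
#' shift. A perfect localizer places all mass at shift 0; a fully captured
#' ventriloquist trial set with flashes 4 modules right of the tones places
#' all mass at +4.
#'
#' @param predicted,truth Equal-length integer vectors of module ids.
#' @param geometry Optional [array_geometry()]; when supplied a
#'   `shift_deg` column converts shifts to degrees.
#' @return Data.frame with columns `shift_modules`, `relative_frequency`
#'   (summing to 1) and optionally `shift_deg`; zero-frequency interior
#'   shifts are kept.
#' @export
shift_histogram <- function(predicted, truth, geometry = NULL) {
  if (length(predicted) != length(truth))
    stop("`predicted` and `truth` must have equal length")
  if (length(predicted) == 0L) stop("no trials")
  shift <- as.integer(predicted) - as.integer(truth)
  rng <- seq(min(shift), max(shift))
  freq <- tabulate(shift - min(shift) + 1L, nbins = length(rng)) / length(shift)
  out <- data.frame(shift_modules = rng, relative_frequency = freq)
  if (!is.null(geometry)) out$shift_deg <- modules_to_degrees(rng, geometry)
  out
}
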