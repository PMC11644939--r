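#' Stereo camera model
#'
#' Describes the pinhole/stereo geometry of a top-down mounted RGB-D camera:
#' the focal length expressed in pixels (physical focal length times the
#' sensor's pixels-per-millimetre conversion), the stereo baseline (physical
#' distance between the two sensors), the frame dimensions, and the nominal
#' mounting height above the tray plane.
#'
#' @param focal_length_px Focal length in pixels (> 0).
#' @param baseline_mm Distance between the two stereo sensors in mm (> 0).
#' @param width_px,height_px Frame dimensions in pixels (>= 1).
#' @param mount_height_mm Nominal camera-to-tray distance in mm; default 1200
#'   (camera mounted roughly 1.2 m above the tray).
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(focal_length_px = 400, baseline_mm = 75,
#'                     width_px = 64, height_px = 48)
#' @export
camera_model <- function(focal_length_px, baseline_mm, width_px, height_px,
                         mount_height_mm = 1200) {
  stopifnot(is.numeric(focal_length_px), length(focal_length_px) == 1L)
  if (!is.finite(focal_length_px) || focal_length_px <= 0)
    stop("focal_length_px must be a positive finite number")
  if (!is.finite(baseline_mm) || baseline_mm <= 0)
    stop("baseline_mm must be a positive finite number")
  if (width_px < 1 || height_px < 1)
    stop("frame dimensions must be >= 1 pixel")
  if (!is.finite(mount_height_mm) || mount_height_mm <= 0)
    stop("mount_height_mm must be positive")
  structure(list(
    focal_length_px = as.numeric(focal_length_px),
    baseline_mm = as.numeric(baseline_mm),
    width_px = as.integer(width_px),
    height_px = as.integer(height_px),
    mount_height_mm = as.numeric(mount_height_mm)
  ), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> f = %.1f px, baseline = %.1f mm, %d x %d px, mount %.0f mm\n",
    x$focal_length_px, x$baseline_mm, x$width_px, x$height_px,
    x$mount_height_mm))
  invisible(x)
}

#' Disparity frame
#'
#' A grid of stereo disparities in pixels. Disparity 0 is the sentinel for
#' "no stereo match"; it is the only invalid marker at the disparity level.
#' An optional per-pixel confidence grid (integers 0-255) supports
#' confidence gating.
#'
#' Grids are stored as R matrices indexed `[row, col]`; the public pixel
#' coordinate convention everywhere in the package is 0-based `(u, v)` =
#' (column, row) with origin at the top-left, so pixel `(u, v)` lives at
#' `values[v + 1, u + 1]`.
#'
#' @param values Numeric matrix of disparities in pixels (all >= 0).
#' @param confidence Optional integer matrix (0-255), same shape.
#' @return An object of class `disparity_frame`.
#' @export
disparity_frame <- function(values, confidence = NULL) {
  if (!is.matrix(values)) stop("disparity values must be a matrix")
  if (any(!is.finite(values)) || any(values < 0))
    stop("disparities must be finite and >= 0 (0 encodes no stereo match)")
  if (!is.null(confidence)) {
    if (!is.matrix(confidence) || !identical(dim(confidence), dim(values)))
      stop("confidence grid must be a matrix with the same shape as values")
    if (any(confidence < 0 | confidence > 255))
      stop("confidence values must lie in [0, 255]")
  }
  structure(list(values = values, confidence = confidence),
            class = "disparity_frame")
}

#' Depth frame
#'
#' A grid of depths in mm with an explicit boolean validity grid. Invalid
#' pixels hold `NA` in `values` and `FALSE` in `valid`; they are never
#' silently zero-filled into downstream sums.
#'
#' @param values Numeric matrix of depths in mm; `NA` marks invalid pixels.
#' @param valid Optional logical matrix; derived from `is.na(values)` when
#'   omitted.
#' @param timestamp Optional capture time in seconds.
#' @return An object of class `depth_frame`.
#' @export
depth_frame <- function(values, valid = NULL, timestamp = NULL) {
  if (!is.matrix(values)) stop("depth values must be a matrix")
  if (is.null(valid)) {
    valid <- !is.na(values) & is.finite(values)
  } else {
    if (!is.logical(valid) || !identical(dim(valid), dim(values)))
      stop("valid must be a logical matrix with the same shape as values")
  }
  values[!valid] <- NA_real_
  v <- values[valid]
  if (length(v) && (any(!is.finite(v)) || any(v < 0)))
    stop("valid depths must be finite and >= 0")
  structure(list(values = values, valid = valid, timestamp = timestamp),
            class = "depth_frame")
}

#' @export
print.depth_frame <- function(x, ...) {
  cat(sprintf("<depth_frame> %d x %d px, %.1f%% valid, range [%s, %s] mm\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$valid),
              format(suppressWarnings(min(x$values, na.rm = TRUE))),
              format(suppressWarnings(max(x$values, na.rm = TRUE)))))
  invisible(x)
}

#' Depth post-processing configuration
#'
#' Bundles the depth-camera filter settings applied between capture and
#' volume integration: a median filter kernel, a temporal exponential
#' moving-average coefficient, an edge-aware spatial smoother
#' (alpha/radius/delta, run for a fixed number of iterations), a stereo
#' confidence threshold and a frame decimation factor. Defaults mirror a
#' typical stereo depth camera configuration for this task: 7x7 median,
#' alphas 0.1, radius 2, delta 0 with four iterations, confidence 200,
#' decimation 2.
#'
#' @param median_kernel Odd window size (pixels) for the median filter.
#' @param temporal_alpha EMA coefficient in (0, 1].
#' @param spatial_alpha Spatial smoother coefficient in (0, 1]; 1 disables
#'   smoothing.
#' @param spatial_radius Neighbourhood radius in pixels.
#' @param spatial_delta Edge threshold in mm; 0 means no edge threshold
#'   (pure smoothing).
#' @param spatial_iterations Number of horizontal+vertical smoothing passes.
#' @param confidence_threshold Stereo confidence gate in 0-255.
#' @param decimation_factor Keep every `decimation_factor`-th frame (>= 1).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(median_kernel = 7, temporal_alpha = 0.1,
                          spatial_alpha = 0.1, spatial_radius = 2,
                          spatial_delta = 0, spatial_iterations = 4,
                          confidence_threshold = 200, decimation_factor = 2) {
  median_kernel <- as.integer(median_kernel)
  if (median_kernel < 1L || median_kernel %% 2L == 0L)
    stop("median_kernel must be an odd integer >= 1")
  if (temporal_alpha <= 0 || temporal_alpha > 1)
    stop("temporal_alpha must lie in (0, 1]")
  if (spatial_alpha <= 0 || spatial_alpha > 1)
    stop("spatial_alpha must lie in (0, 1]")
  if (spatial_radius < 0) stop("spatial_radius must be >= 0")
  if (spatial_delta < 0) stop("spatial_delta must be >= 0")
  if (spatial_iterations < 0) stop("spatial_iterations must be >= 0")
  if (confidence_threshold < 0 || confidence_threshold > 255)
    stop("confidence_threshold must lie in [0, 255]")
  if (decimation_factor < 1) stop("decimation_factor must be >= 1")
  structure(list(
    median_kernel = median_kernel,
    temporal_alpha = temporal_alpha,
    spatial_alpha = spatial_alpha,
    spatial_radius = as.integer(spatial_radius),
    spatial_delta = spatial_delta,
    spatial_iterations = as.integer(spatial_iterations),
    confidence_threshold = confidence_threshold,
    decimation_factor = as.integer(decimation_factor)
  ), class = "filter_config")
}

check_frame_dims <- function(values, cam) {
  if (nrow(values) != cam$height_px || ncol(values) != cam$width_px)
    stop(sprintf(
      "frame shape %d x %d (rows x cols) does not match camera %d x %d",
      nrow(values), ncol(values), cam$height_px, cam$width_px))
  invisible(TRUE)
}

#' Convert a disparity frame to depth
#'
#' Applies the stereo triangulation relation
#' `depth = focal_length_px * baseline_mm / disparity_px` per pixel.
#' Pixels with disparity 0 (no stereo match) become invalid depth pixels
#' rather than infinities.
#'
#' @param disp A [disparity_frame()].
#' @param cam A [camera_model()] whose dimensions match `disp`.
#' @return A [depth_frame()] in mm.
#' @examples
#' cam <- camera_model(400, 75, 4, 3)
#' d <- disparity_frame(matrix(25, 3, 4))
#' disparity_to_depth(d, cam)$values[1, 1]  # 1200 mm
#' @export
disparity_to_depth <- function(disp, cam) {
  stopifnot(inherits(disp, "disparity_frame"), inherits(cam, "camera_model"))
  check_frame_dims(disp$values, cam)
  d <- disp$values
  depth <- matrix(NA_real_, nrow(d), ncol(d))
  pos <- d > 0
  depth[pos] <- cam$focal_length_px * cam$baseline_mm / d[pos]
  depth_frame(depth)
}

#' Convert a depth frame to disparity
#'
#' Algebraic inverse of [disparity_to_depth()]:
#' `disparity = focal_length_px * baseline_mm / depth`. Invalid depth pixels
#' map to the disparity sentinel 0. Used by the scene simulator's stereo
#' quantization model.
#'
#' @param depth A [depth_frame()] with strictly positive valid depths.
#' @param cam A [camera_model()] whose dimensions match `depth`.
#' @return A [disparity_frame()].
#' @export
depth_to_disparity <- function(depth, cam) {
  stopifnot(inherits(depth, "depth_frame"), inherits(cam, "camera_model"))
  check_frame_dims(depth$values, cam)
  z <- depth$values
  if (any(z[depth$valid] <= 0))
    stop("all valid depths must be > 0 to form a disparity")
  d <- matrix(0, nrow(z), ncol(z))
  d[depth$valid] <- cam$focal_length_px * cam$baseline_mm / z[depth$valid]
  disparity_frame(d)
}
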