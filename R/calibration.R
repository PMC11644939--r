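# Pixel->millimetre calibration, reference-plane depth, and the flat-surface
# capture check run before a measurement session.

#' Pixel-to-millimetre conversion factor
#'
#' The ground-sampling distance of a pinhole camera at a given working
#' distance: `kpix = distance_mm / focal_length_px` (mm per pixel). One
#' `kpix` is computed per scene at the tray reference depth; `kpix^2`
#' converts pixel area to mm^2 during volume integration.
#'
#' @param cam A [camera_model()].
#' @param distance_mm Camera-to-plane distance in mm (> 0); defaults to the
#'   camera's mount height.
#' @return An object of class `pixel_scale` with fields `kpix` and
#'   `reference_depth_mm`.
#' @examples
#' compute_kpix(camera_model(400, 75, 64, 48), 1200)$kpix  # 3 mm/px
#' @export
compute_kpix <- function(cam, distance_mm = cam$mount_height_mm) {
  stopifnot(inherits(cam, "camera_model"))
  if (!is.finite(distance_mm) || distance_mm <= 0)
    stop("distance_mm must be positive")
  structure(list(kpix = distance_mm / cam$focal_length_px,
                 reference_depth_mm = distance_mm),
            class = "pixel_scale")
}

#' Construct a pixel scale directly
#'
#' Mainly useful when the conversion factor is known from an external
#' calibration rather than derived from the camera model.
#'
#' @param kpix mm per pixel (> 0).
#' @param reference_depth_mm Distance at which `kpix` holds (> 0).
#' @return An object of class `pixel_scale`.
#' @export
pixel_scale <- function(kpix, reference_depth_mm) {
  if (kpix <= 0 || reference_depth_mm <= 0)
    stop("kpix and reference_depth_mm must be > 0")
  structure(list(kpix = kpix, reference_depth_mm = reference_depth_mm),
            class = "pixel_scale")
}

#' Pick the session reference-point depth
#'
#' The reference point (RP) is a fixed tray-plane pixel chosen once per
#' session; its depth defines the zero-height plane that food surfaces are
#' measured against. To resist speckle, the depth is taken as the median of
#' the valid depths in the `(2 * window + 1)^2` neighbourhood of `(u, v)`.
#'
#' @param depth A [depth_frame()].
#' @param u,v 0-based pixel coordinates (column, row) inside the frame.
#' @param window Half-width of the median window in pixels (default 2).
#' @return An object of class `reference_point` with fields `u`, `v`,
#'   `depth_mm`.
#' @export
pick_reference_depth <- function(depth, u, v, window = 2) {
  stopifnot(inherits(depth, "depth_frame"))
  window <- as.integer(window)
  if (window < 0L) stop("window must be >= 0")
  nr <- nrow(depth$values); nc <- ncol(depth$values)
  if (u < 0 || u >= nc || v < 0 || v >= nr)
    stop(sprintf("reference point (u=%d, v=%d) outside %d x %d frame",
                 u, v, nc, nr))
  rs <- max(1L, v + 1L - window):min(nr, v + 1L + window)
  cs <- max(1L, u + 1L - window):min(nc, u + 1L + window)
  vals <- depth$values[rs, cs]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop("no valid depth pixels in the reference window; reference unavailable")
  structure(list(u = as.integer(u), v = as.integer(v),
                 depth_mm = stats::median(vals)),
            class = "reference_point")
}

#' Flat-surface capture check
#'
#' Session sanity check run on a capture of an empty flat surface (the bare
#' tray): reports the mean, standard deviation and maximum absolute residual
#' of the valid depths about their mean, and whether the maximum residual is
#' within tolerance. No plane is fitted; the camera is assumed mounted
#' parallel to the tray.
#'
#' @param depth A [depth_frame()] with at least 50% valid pixels.
#' @param tolerance_mm Maximum tolerated |depth - mean| in mm.
#' @return An object of class `flatness_report` with fields `mean_depth_mm`,
#'   `std_depth_mm`, `max_abs_residual_mm`, `passed`, `tolerance_mm`,
#'   `valid_fraction`.
#' @export
check_flat_surface <- function(depth, tolerance_mm) {
  stopifnot(inherits(depth, "depth_frame"))
  if (tolerance_mm < 0) stop("tolerance_mm must be >= 0")
  frac <- mean(depth$valid)
  if (frac < 0.5)
    stop(sprintf("only %.1f%% of pixels are valid (< 50%%); capture unusable",
                 100 * frac))
  vals <- depth$values[depth$valid]
  m <- mean(vals)
  resid <- abs(vals - m)
  structure(list(
    mean_depth_mm = m,
    std_depth_mm = if (length(vals) > 1L) stats::sd(vals) else 0,
    max_abs_residual_mm = max(resid),
    passed = max(resid) <= tolerance_mm,
    tolerance_mm = tolerance_mm,
    valid_fraction = frac
  ), class = "flatness_report")
}

#' @export
print.flatness_report <- function(x, ...) {
  cat(sprintf(
    "<flatness_report> mean %.2f mm, sd %.2f mm, max |resid| %.2f mm (tol %.2f): %s\n",
    x$mean_depth_mm, x$std_depth_mm, x$max_abs_residual_mm, x$tolerance_mm,
    if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}
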