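# Synthetic top-down tray scenes with analytic ground truth. The renderer is
# orthographic at the tray ground-sampling distance, matching the single-kpix
# surface-integration model the pipeline implements, so every deviation the
# tests observe is attributable to the pipeline, not to a projection
# mismatch. Stereo imperfections are modelled in the disparity domain:
# subpixel quantization, Gaussian matching noise, and low-texture dropout
# (invalidated or flattened regions).

#' Stereo noise specification
#'
#' @param disparity_quantization_px Subpixel disparity step (e.g. 1/8 px);
#'   0 disables quantization.
#' @param gaussian_depth_sigma_mm Depth-equivalent Gaussian matching noise
#'   at the tray distance; applied as its disparity-domain equivalent so the
#'   resulting depth error grows quadratically with distance, as stereo
#'   error does. 0 disables.
#' @param dropout_regions List of dropout descriptors, each a list with
#'   `region` (either `list(type = "rect", u0, v0, u1, v1)` in 0-based
#'   half-open pixel coordinates, or `list(type = "class_top", class_label,
#'   min_height_mm)` selecting a solid's pixels above a height) and `mode`
#'   (`"invalid"`, or `list(flatten_to = <depth mm>)` which pins the depth,
#'   emulating stereo failure on low-texture tops that come out flattened).
#' @param seed Integer seed; all randomness flows through it.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(disparity_quantization_px = 0,
                       gaussian_depth_sigma_mm = 0,
                       dropout_regions = list(), seed = 1) {
  if (disparity_quantization_px < 0 || gaussian_depth_sigma_mm < 0)
    stop("noise magnitudes must be >= 0")
  structure(list(disparity_quantization_px = disparity_quantization_px,
                 gaussian_depth_sigma_mm = gaussian_depth_sigma_mm,
                 dropout_regions = dropout_regions,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Scene specification
#'
#' A top-down tray scene: a flat tray reference plane at `tray_depth_mm`
#' below the camera, a set of non-overlapping food solids standing on it,
#' and optionally a plate modelled as an annular rim of positive height
#' (so the below-plane/clamping behaviour of the volume stage can be
#' exercised by placing the reference plane at the rim).
#'
#' @param camera A [camera_model()].
#' @param tray_depth_mm Camera-to-tray distance in mm (ground-truth RP);
#'   defaults to the camera mount height.
#' @param solids List of [solid_spec()]s with pairwise non-overlapping
#'   footprints.
#' @param plate Optional list `list(radius, rim_width, rim_height,
#'   center = c(x, y))` in mm.
#' @param noise A [noise_spec()].
#' @param background_color,plate_color RGB triplets in `[0, 1]`.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(camera, tray_depth_mm = camera$mount_height_mm,
                       solids = list(), plate = NULL, noise = noise_spec(),
                       background_color = c(0.35, 0.35, 0.35),
                       plate_color = c(0.95, 0.95, 0.92)) {
  stopifnot(inherits(camera, "camera_model"))
  if (tray_depth_mm <= 0) stop("tray_depth_mm must be > 0")
  stopifnot(all(vapply(solids, inherits, TRUE, "solid_spec")))
  if (length(solids) > 1L) {
    for (i in seq_along(solids)[-length(solids)])
      for (j in (i + 1L):length(solids)) {
        d <- sqrt(sum((solids[[i]]$center - solids[[j]]$center)^2))
        if (d < footprint_radius(solids[[i]]) + footprint_radius(solids[[j]]))
          stop(sprintf("solids '%s' and '%s' have overlapping footprints",
                       solids[[i]]$class_label, solids[[j]]$class_label))
      }
  }
  # footprints must lie inside the rendered frame: a clipped solid would be
  # integrated against a truth volume it cannot reach
  kpix <- tray_depth_mm / camera$focal_length_px
  half_w <- camera$width_px / 2 * kpix
  half_h <- camera$height_px / 2 * kpix
  for (s in solids) {
    r <- footprint_radius(s)
    if (abs(s$center[1L]) + r > half_w + 1e-9 ||
        abs(s$center[2L]) + r > half_h + 1e-9)
      stop(sprintf(
        "solid '%s' footprint (radius %.1f mm at [%.0f, %.0f]) extends beyond the %.0f x %.0f mm frame",
        s$class_label, r, s$center[1L], s$center[2L], 2 * half_w, 2 * half_h))
  }
  structure(list(camera = camera, tray_depth_mm = tray_depth_mm,
                 solids = solids, plate = plate, noise = noise,
                 background_color = background_color,
                 plate_color = plate_color),
            class = "scene_spec")
}

#' Render a synthetic tray scene
#'
#' Samples the scene height field orthographically on the pixel grid with
#' spacing `kpix = tray_depth_mm / focal_length_px`: pixel `(u, v)` sees
#' `depth = tray_depth - height(x, y)` at the tray-plane point below it.
#' Produces the depth frame, a flat-colour RGB frame (background / plate /
#' per-solid palette colours), a full-confidence grid, exact per-class
#' ground-truth masks, and the closed-form ground-truth volume of every
#' solid.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `render_bundle` with elements `depth`, `rgb`,
#'   `confidence`, `masks`, `truth_volumes_mm3` (named), `kpix`, `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  cam <- spec$camera
  kpix <- spec$tray_depth_mm / cam$focal_length_px
  nr <- cam$height_px; nc <- cam$width_px
  # tray-plane coordinates of pixel centres, frame-centred, mm
  xs <- ((seq_len(nc) - 1L) + 0.5 - nc / 2) * kpix
  ys <- ((seq_len(nr) - 1L) + 0.5 - nr / 2) * kpix
  X <- matrix(rep(xs, each = nr), nr, nc)
  Y <- matrix(rep(ys, times = nc), nr, nc)
  height <- matrix(0, nr, nc)
  rgb <- array(0, dim = c(nr, nc, 3L))
  for (ch in 1:3) rgb[, , ch] <- spec$background_color[ch]
  if (!is.null(spec$plate)) {
    p <- spec$plate
    ctr <- if (is.null(p$center)) c(0, 0) else p$center
    r <- sqrt((X - ctr[1L])^2 + (Y - ctr[2L])^2)
    rim <- r <= p$radius & r >= p$radius - p$rim_width
    disc <- r <= p$radius
    height[rim] <- pmax(height[rim], p$rim_height)
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[disc] <- spec$plate_color[ch]
      rgb[, , ch] <- plane
    }
  }
  masks <- list()
  for (s in spec$solids) {
    hs <- matrix(solid_height(s, as.vector(X), as.vector(Y)), nr, nc)
    inside <- hs > 0
    if (!any(inside))
      stop(sprintf("solid '%s' has no pixel footprint in the frame",
                   s$class_label))
    height <- pmax(height, hs)
    masks[[length(masks) + 1L]] <- segmentation_mask(s$class_label, inside)
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[inside] <- s$color[ch]
      rgb[, , ch] <- plane
    }
  }
  depth <- depth_frame(spec$tray_depth_mm - height)
  conf <- matrix(255L, nr, nc)
  truth <- vapply(spec$solids, analytic_volume, numeric(1L))
  names(truth) <- vapply(spec$solids, function(s) s$class_label, character(1L))
  structure(list(depth = depth, rgb = rgb, confidence = conf, masks = masks,
                 truth_volumes_mm3 = truth, kpix = kpix, spec = spec),
            class = "render_bundle")
}

#' Palette of a rendered scene
#'
#' Named list of solid colours suitable for [colorkey_segment()].
#'
#' @param spec A [scene_spec()] (or a `render_bundle`'s `spec`).
#' @return Named list of RGB triplets.
#' @export
scene_palette <- function(spec) {
  if (inherits(spec, "render_bundle")) spec <- spec$spec
  stats::setNames(lapply(spec$solids, function(s) s$color),
                  vapply(spec$solids, function(s) s$class_label,
                         character(1L)))
}

#' Apply stereo imperfections to a rendered bundle
#'
#' Converts depth to disparity, rounds to the quantization step, adds the
#' disparity-domain equivalent of the configured Gaussian depth noise
#' (`sigma_d = sigma_z * d^2 / (f B)` evaluated per pixel, so depth error
#' grows quadratically with distance), converts back, then applies dropout
#' regions: `"invalid"` removes the pixels, `flatten_to` pins their depth,
#' reproducing the flattened tops that stereo matching produces on
#' low-texture surfaces. Deterministic under the spec's seed; a zero noise
#' spec returns the bundle unchanged.
#'
#' @param bundle A `render_bundle` from [render_scene()].
#' @param noise A [noise_spec()]; defaults to the one in the bundle's scene.
#' @return A `render_bundle` with perturbed depth (ground truth untouched).
#' @export
apply_stereo_noise <- function(bundle, noise = bundle$spec$noise) {
  stopifnot(inherits(bundle, "render_bundle"), inherits(noise, "noise_spec"))
  cam <- bundle$spec$camera
  z <- bundle$depth$values
  valid <- bundle$depth$valid
  fB <- cam$focal_length_px * cam$baseline_mm
  if (noise$disparity_quantization_px > 0 || noise$gaussian_depth_sigma_mm > 0) {
    d <- matrix(0, nrow(z), ncol(z))
    d[valid] <- fB / z[valid]
    if (noise$disparity_quantization_px > 0) {
      q <- noise$disparity_quantization_px
      d[valid] <- round(d[valid] / q) * q
    }
    if (noise$gaussian_depth_sigma_mm > 0) {
      set.seed(noise$seed)
      sigma_d <- noise$gaussian_depth_sigma_mm * d[valid]^2 / fB
      d[valid] <- pmax(d[valid] + stats::rnorm(sum(valid), 0, sigma_d),
                       .Machine$double.eps)
    }
    z[valid] <- fB / d[valid]
  }
  for (dr in noise$dropout_regions) {
    sel <- dropout_selector(dr$region, bundle)
    if (identical(dr$mode, "invalid")) {
      z[sel] <- NA_real_
      valid <- valid & !sel
    } else if (is.list(dr$mode) && !is.null(dr$mode$flatten_to)) {
      z[sel & valid] <- dr$mode$flatten_to
    } else stop("dropout mode must be \"invalid\" or list(flatten_to = mm)")
  }
  out <- bundle
  out$depth <- depth_frame(z, valid, bundle$depth$timestamp)
  out$noise_applied <- noise
  out
}

dropout_selector <- function(region, bundle) {
  nr <- nrow(bundle$depth$values); nc <- ncol(bundle$depth$values)
  if (identical(region$type, "rect")) {
    sel <- matrix(FALSE, nr, nc)
    rs <- (max(0L, region$v0):min(nr - 1L, region$v1 - 1L)) + 1L
    cs <- (max(0L, region$u0):min(nc - 1L, region$u1 - 1L)) + 1L
    sel[rs, cs] <- TRUE
    sel
  } else if (identical(region$type, "class_top")) {
    m <- NULL
    for (mk in bundle$masks)
      if (mk$class_label == region$class_label) m <- mk$mask
    if (is.null(m))
      stop(sprintf("no mask for class '%s' in bundle", region$class_label))
    h <- bundle$spec$tray_depth_mm - bundle$depth$values
    h[is.na(h)] <- 0
    m & h > region$min_height_mm
  } else stop("unknown dropout region type")
}

#' Synthesize a volume-weight training set
#'
#' Draws volumes uniformly over a range and generates weights from a known
#' law plus Gaussian noise, emulating a portion-weighing study. Two laws are
#' provided: `"linear"` (`w = slope * V + intercept`, the regime of
#' granular, near-constant-density foods such as rice) and `"sigmoid"`
#' (`w = w_base + w_span / (1 + exp(-(V - v_mid) / v_scale))`, a smooth
#' nonlinear regime emulating irregular proteins whose density and shape
#' vary with portion size). The true law is recorded in attributes for
#' oracle checks. Noise is additive (`+ eps`) by default or multiplicative
#' (`* (1 + eps)`) on request.
#'
#' @param n Number of records (>= 4).
#' @param law `list(type = "linear", slope, intercept)` or
#'   `list(type = "sigmoid", w_base, w_span, v_mid, v_scale)`; sensible
#'   defaults fill missing entries.
#' @param noise_sigma_g Gaussian noise sd in grams (additive) or relative
#'   units (multiplicative).
#' @param seed Integer seed.
#' @param volume_range Length-2 range of volumes in mm^3.
#' @param noise_mode `"additive"` or `"multiplicative"`.
#' @param class_label Class recorded on every row.
#' @return A [volume_weight_set()] with attributes `true_law` (a function
#'   of volume) and `law_spec`.
#' @export
generate_weight_dataset <- function(n, law = list(type = "linear"),
                                    noise_sigma_g = 0, seed = 1,
                                    volume_range = NULL,
                                    noise_mode = c("additive", "multiplicative"),
                                    class_label = law$type) {
  if (n < 4L) stop("need n >= 4 records")
  noise_mode <- match.arg(noise_mode)
  if (law$type == "linear") {
    if (is.null(law$slope)) law$slope <- 8e-4       # ~cooked-grain density, g/mm^3
    if (is.null(law$intercept)) law$intercept <- 0
    if (is.null(volume_range)) volume_range <- c(1e5, 4e5)
    f <- function(v) law$slope * v + law$intercept
  } else if (law$type == "sigmoid") {
    if (is.null(law$w_base)) law$w_base <- 80
    if (is.null(law$w_span)) law$w_span <- 180
    if (is.null(law$v_mid)) law$v_mid <- 2.5e5
    if (is.null(law$v_scale)) law$v_scale <- 3.5e4
    if (is.null(volume_range)) volume_range <- c(1.5e5, 3.5e5)
    f <- function(v) law$w_base + law$w_span /
      (1 + exp(-(v - law$v_mid) / law$v_scale))
  } else stop("law$type must be \"linear\" or \"sigmoid\"")
  set.seed(seed)
  v <- stats::runif(n, volume_range[1L], volume_range[2L])
  w <- f(v)
  if (noise_sigma_g > 0) {
    eps <- stats::rnorm(n, 0, noise_sigma_g)
    w <- if (noise_mode == "additive") w + eps else w * (1 + eps)
  }
  w <- pmax(w, 1e-6)
  out <- volume_weight_set(v, w, class_label = class_label)
  attr(out, "true_law") <- f
  attr(out, "law_spec") <- law
  out
}
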