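# Parametric food-solid stand-ins used by the scene renderer and the voxel
# test oracle. All solids are height fields over the tray plane: the solid
# occupies {(x, y, z): 0 <= z <= height(x, y)}.

#' Parametric solid specification
#'
#' Four height-field solids stand in for plated food geometry:
#' `spherical_cap` (dome of sphere radius `R`, cap height `h`; e.g. a rice
#' mound), `cylinder` (`radius`, `height`), `cuboid` (`x_mm`, `y_mm`,
#' `height`) and `frustum` (truncated cone: `r_base`, `r_top`, `height`).
#' Dimensions are mm; `center` places the solid on the tray plane in mm
#' relative to the frame centre.
#'
#' @param shape One of `"spherical_cap"`, `"cylinder"`, `"cuboid"`,
#'   `"frustum"`.
#' @param ... Shape parameters (see Details above), all > 0; for
#'   `spherical_cap`, `h <= R` is required.
#' @param center Length-2 numeric, tray-plane position of the solid centre
#'   in mm.
#' @param class_label Class name used for masks and reports.
#' @param color Length-3 RGB palette colour in `[0, 1]` for rendering.
#' @return An object of class `solid_spec`.
#' @examples
#' solid_spec("spherical_cap", R = 60, h = 40, class_label = "rice")
#' @export
solid_spec <- function(shape = c("spherical_cap", "cylinder", "cuboid", "frustum"),
                       ..., center = c(0, 0), class_label = shape,
                       color = c(1, 0, 0)) {
  shape <- match.arg(shape)
  p <- list(...)
  need <- switch(shape,
                 spherical_cap = c("R", "h"),
                 cylinder = c("radius", "height"),
                 cuboid = c("x_mm", "y_mm", "height"),
                 frustum = c("r_base", "r_top", "height"))
  if (!all(need %in% names(p)))
    stop(sprintf("shape '%s' requires parameters: %s", shape,
                 paste(need, collapse = ", ")))
  p <- p[need]
  if (any(unlist(p) <= 0)) stop("all solid dimensions must be > 0")
  if (shape == "spherical_cap" && p$h > p$R)
    stop("spherical cap requires h <= R")
  if (shape == "frustum" && p$r_top > p$r_base)
    stop("frustum requires r_top <= r_base")
  structure(list(shape = shape, params = p, center = as.numeric(center),
                 class_label = as.character(class_label)[1L],
                 color = as.numeric(color)),
            class = "solid_spec")
}

#' Closed-form volume of a parametric solid
#'
#' Spherical cap `pi h^2 (3R - h) / 3`; cylinder `pi r^2 h`; cuboid `a b c`;
#' frustum `pi h (R^2 + R r + r^2) / 3`.
#'
#' @param solid A [solid_spec()].
#' @return Volume in mm^3.
#' @export
analytic_volume <- function(solid) {
  stopifnot(inherits(solid, "solid_spec"))
  p <- solid$params
  switch(solid$shape,
         spherical_cap = pi * p$h^2 * (3 * p$R - p$h) / 3,
         cylinder = pi * p$radius^2 * p$height,
         cuboid = p$x_mm * p$y_mm * p$height,
         frustum = pi * p$height * (p$r_base^2 + p$r_base * p$r_top +
                                      p$r_top^2) / 3)
}

#' Height field of a solid
#'
#' Evaluates the solid's surface height (mm above the tray plane) at
#' tray-plane points `(x, y)` in mm; 0 outside the footprint. Vectorised
#' over `x`/`y`.
#'
#' @param solid A [solid_spec()].
#' @param x,y Numeric vectors of tray-plane coordinates in mm.
#' @return Numeric vector of heights in mm.
#' @export
solid_height <- function(solid, x, y) {
  stopifnot(inherits(solid, "solid_spec"))
  dx <- x - solid$center[1L]; dy <- y - solid$center[2L]
  p <- solid$params
  h <- numeric(length(dx))
  if (solid$shape == "spherical_cap") {
    r2 <- dx^2 + dy^2
    a2 <- p$h * (2 * p$R - p$h)  # footprint radius^2
    inside <- r2 <= a2
    h[inside] <- sqrt(p$R^2 - r2[inside]) - (p$R - p$h)
  } else if (solid$shape == "cylinder") {
    inside <- dx^2 + dy^2 <= p$radius^2
    h[inside] <- p$height
  } else if (solid$shape == "cuboid") {
    inside <- abs(dx) <= p$x_mm / 2 & abs(dy) <= p$y_mm / 2
    h[inside] <- p$height
  } else {  # frustum: full height inside r_top, linear taper to 0 at r_base
    r <- sqrt(dx^2 + dy^2)
    top <- r <= p$r_top
    slope <- r > p$r_top & r <= p$r_base
    h[top] <- p$height
    h[slope] <- p$height * (p$r_base - r[slope]) / (p$r_base - p$r_top)
  }
  h
}

#' Footprint radius of a solid
#'
#' Radius (mm) of the smallest circle centred at the solid's centre that
#' contains its footprint; used for the non-overlap check.
#'
#' @param solid A [solid_spec()].
#' @return Radius in mm.
#' @export
footprint_radius <- function(solid) {
  p <- solid$params
  switch(solid$shape,
         spherical_cap = sqrt(p$h * (2 * p$R - p$h)),
         cylinder = p$radius,
         cuboid = sqrt(p$x_mm^2 + p$y_mm^2) / 2,
         frustum = p$r_base)
}

#' Brute-force voxel volume oracle
#'
#' Counts voxel centres lying inside the solid on a regular grid of pitch
#' `voxel_mm` and multiplies by the voxel volume. Converges to the analytic
#' volume as `voxel_mm` shrinks; used as an implementation-independent
#' cross-check of the surface-integration pipeline.
#'
#' @param solid A [solid_spec()].
#' @param voxel_mm Voxel edge length in mm (> 0).
#' @return Estimated volume in mm^3.
#' @export
voxel_volume_oracle <- function(solid, voxel_mm) {
  stopifnot(inherits(solid, "solid_spec"))
  if (voxel_mm <= 0) stop("voxel_mm must be > 0")
  a <- footprint_radius(solid)
  hmax <- switch(solid$shape,
                 spherical_cap = solid$params$h,
                 cylinder = solid$params$height,
                 cuboid = solid$params$height,
                 frustum = solid$params$height)
  # voxel centres spanning the footprint bounding box, solid-centred; an
  # even count keeps centres at half-integer multiples of the pitch so they
  # never land exactly on an axis-aligned face
  nx <- 2L * (ceiling(a / voxel_mm) + 1L)
  xs <- (seq_len(nx) - nx / 2 - 0.5) * voxel_mm + solid$center[1L]
  ys <- (seq_len(nx) - nx / 2 - 0.5) * voxel_mm + solid$center[2L]
  g <- expand.grid(x = xs, y = ys)
  hxy <- solid_height(solid, g$x, g$y)
  nz <- ceiling(hmax / voxel_mm) + 1L
  count <- 0
  for (k in seq_len(nz)) {
    zc <- (k - 0.5) * voxel_mm
    count <- count + sum(hxy > zc)
  }
  count * voxel_mm^3
}
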