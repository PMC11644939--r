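# Mask-gated volume integration: per-pixel surface heights above the tray
# reference plane, summed to mm^3 via the pixel-area conversion kpix^2, with
# a regular-grid height mesh for visualisation.

#' Per-pixel surface contribution of a masked food item
#'
#' For every pixel inside the segmentation mask, the height of the food
#' surface above the reference plane is `RP - depth_sat` (food rises toward
#' the camera, so its depth is smaller than the tray's). Pixels outside the
#' mask contribute 0. Negative contributions (below-plane returns: concave
#' plate interior, sensor noise) are clamped to 0 and counted rather than
#' subtracted; masked pixels with invalid depth contribute 0 and are counted
#' separately so callers can reject frames with excessive dropout.
#'
#' @param depth_sat A saturated [depth_frame()] (see [saturate_depth()]).
#' @param mask A [segmentation_mask()] of the same shape.
#' @param ref A [reference_point] from [pick_reference_depth()], or a single
#'   depth in mm.
#' @param scale A `pixel_scale` from [compute_kpix()].
#' @return An object of class `surface_map` with the height grid `sup` (mm),
#'   the pixel scale, the reference, and the bookkeeping counts.
#' @export
surface_contribution <- function(depth_sat, mask, ref, scale) {
  stopifnot(inherits(depth_sat, "depth_frame"),
            inherits(mask, "segmentation_mask"),
            inherits(scale, "pixel_scale"))
  if (!identical(dim(depth_sat$values), dim(mask$mask)))
    stop(sprintf("depth %d x %d and mask %d x %d shapes differ",
                 nrow(depth_sat$values), ncol(depth_sat$values),
                 nrow(mask$mask), ncol(mask$mask)))
  rp <- if (inherits(ref, "reference_point")) ref$depth_mm else as.numeric(ref)
  in_mask <- mask$mask
  usable <- in_mask & depth_sat$valid
  sup <- matrix(0, nrow(in_mask), ncol(in_mask))
  sup[usable] <- rp - depth_sat$values[usable]
  clamped <- sum(sup[usable] < 0)
  sup[sup < 0] <- 0
  structure(list(
    sup = sup,
    class_label = mask$class_label,
    pixel_scale = scale,
    reference = ref,
    pixel_count = sum(in_mask),
    clamped_negative_count = clamped,
    invalid_in_mask_count = sum(in_mask & !depth_sat$valid)
  ), class = "surface_map")
}

#' Integrate a surface map into a volume
#'
#' `V = sum(sup * kpix^2)` in mm^3: every pixel's height is multiplied by
#' the pixel footprint area at the reference depth and summed.
#'
#' @param sup A `surface_map` from [surface_contribution()].
#' @return An object of class `volume_result` with `class_label`,
#'   `volume_mm3`, `pixel_count`, `clamped_negative_count`,
#'   `invalid_in_mask_count`.
#' @export
integrate_volume <- function(sup) {
  stopifnot(inherits(sup, "surface_map"))
  if (any(!is.finite(sup$sup))) stop("surface map contains non-finite heights")
  structure(list(
    class_label = sup$class_label,
    volume_mm3 = sum(sup$sup) * sup$pixel_scale$kpix^2,
    pixel_count = sup$pixel_count,
    clamped_negative_count = sup$clamped_negative_count,
    invalid_in_mask_count = sup$invalid_in_mask_count
  ), class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf(
    "<volume_result> %s: %.0f mm^3 over %d px (%d clamped, %d invalid)\n",
    x$class_label, x$volume_mm3, x$pixel_count,
    x$clamped_negative_count, x$invalid_in_mask_count))
  invisible(x)
}

#' Per-class dish volumes from a depth frame
#'
#' The full measurement for one frame: saturates the depth map to
#' `[sat_min, sat_max]`, then for each class mask computes the surface
#' contribution relative to the reference point and integrates it to mm^3.
#' Deterministic given its inputs.
#'
#' @param depth A [depth_frame()] (already filtered as desired).
#' @param masks List of [segmentation_mask()]s.
#' @param ref A [reference_point] or depth in mm.
#' @param scale A `pixel_scale` from [compute_kpix()].
#' @param sat_min,sat_max Saturation band in mm.
#' @return A list of `volume_result`s, one per mask.
#' @export
compute_dish_volumes <- function(depth, masks, ref, scale, sat_min, sat_max) {
  dsat <- saturate_depth(depth, sat_min, sat_max)
  lapply(masks, function(m)
    integrate_volume(surface_contribution(dsat, m, ref, scale)))
}

#' Collect volume results into a data frame
#'
#' @param results List of `volume_result`s.
#' @param frame_id Optional frame identifier recycled across rows.
#' @return A `data.frame` with one row per result.
#' @export
volume_report <- function(results, frame_id = NA_character_) {
  if (!length(results))
    return(data.frame(frame_id = character(0), class_label = character(0),
                      volume_mm3 = numeric(0), pixel_count = integer(0),
                      clamped_negative_count = integer(0),
                      invalid_in_mask_count = integer(0)))
  do.call(rbind, lapply(results, function(r)
    data.frame(frame_id = frame_id, class_label = r$class_label,
               volume_mm3 = r$volume_mm3, pixel_count = r$pixel_count,
               clamped_negative_count = r$clamped_negative_count,
               invalid_in_mask_count = r$invalid_in_mask_count,
               stringsAsFactors = FALSE)))
}

#' Build a height mesh from a surface map
#'
#' Regular-grid triangulation of the height field for 3-D visualisation:
#' one vertex per grid point at `(u * kpix, v * kpix, sup)` mm and two
#' triangles per grid cell. Orientation metadata records the conventional
#' top-down view.
#'
#' @param sup A `surface_map`.
#' @return An object of class `height_mesh` with `vertices` (n x 3 matrix,
#'   mm), `faces` (m x 3 matrix of 1-based vertex indices) and `view`.
#' @export
build_mesh <- function(sup) {
  stopifnot(inherits(sup, "surface_map"))
  z <- sup$sup
  nr <- nrow(z); nc <- ncol(z)
  k <- sup$pixel_scale$kpix
  us <- rep(seq_len(nc) - 1L, each = nr)
  vs <- rep(seq_len(nr) - 1L, times = nc)
  vertices <- cbind(x = us * k, y = vs * k, z = as.vector(z))
  # vertex index of grid point (row r, col c), column-major
  idx <- function(r, c) (c - 1L) * nr + r
  faces <- NULL
  if (nr >= 2L && nc >= 2L) {
    r <- rep(seq_len(nr - 1L), times = nc - 1L)
    c <- rep(seq_len(nc - 1L), each = nr - 1L)
    faces <- rbind(
      cbind(idx(r, c), idx(r + 1L, c), idx(r, c + 1L)),
      cbind(idx(r + 1L, c), idx(r + 1L, c + 1L), idx(r, c + 1L)))
  } else {
    faces <- matrix(integer(0), 0L, 3L)
  }
  structure(list(vertices = vertices, faces = faces, view = "top"),
            class = "height_mesh")
}

#' Export a height mesh to Wavefront OBJ
#'
#' @param mesh A `height_mesh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "height_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# height-field mesh, units mm, top view", con)
  writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  if (nrow(mesh$faces))
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                       mesh$faces[, 3L]), con)
  invisible(path)
}

#' Export a height mesh to PLY
#'
#' Binary little-endian by default; ASCII available for inspection.
#'
#' @param mesh A `height_mesh`.
#' @param path Output file path.
#' @param binary Write binary little-endian PLY (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "height_mesh"))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0"
              else "format ascii 1.0",
              "comment height-field mesh, units mm",
              sprintf("element vertex %d", nv),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    writeBin(as.numeric(t(mesh$vertices)), con, size = 4L,
             endian = "little")
    if (nf) for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4L,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.6f %.6f %.6f", mesh$vertices[, 1L],
                       mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
    if (nf)
      writeLines(sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                         mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
  }
  invisible(path)
}
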