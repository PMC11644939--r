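# Segmentation data model. Any mask provider (label image, polygon records,
# colour-key segmentation of synthetic renders, or an external
# detector/segmenter) feeds the same contract: binary per-class masks aligned
# with the depth frame; the pipeline's own computation starts at the mask.

#' Detection records
#'
#' Builds a validated data frame of object detections: one row per detected
#' item with class label, half-open 0-based bounding box
#' `[u_min, u_max) x [v_min, v_max)`, a confidence in `[0, 1]` and an
#' optional timestamp in seconds.
#'
#' @param class_label Character vector of class names.
#' @param u_min,v_min,u_max,v_max Bounding-box pixel coordinates.
#' @param confidence Numeric vector in `[0, 1]`.
#' @param timestamp Optional numeric vector of capture times (s).
#' @return A `data.frame` of class `detection_records`.
#' @export
detection_records <- function(class_label, u_min, v_min, u_max, v_max,
                              confidence, timestamp = NA_real_) {
  n <- length(class_label)
  df <- data.frame(class_label = as.character(class_label),
                   u_min = rep_len(u_min, n), v_min = rep_len(v_min, n),
                   u_max = rep_len(u_max, n), v_max = rep_len(v_max, n),
                   confidence = rep_len(confidence, n),
                   timestamp = rep_len(timestamp, n),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$u_min >= df$u_max) || any(df$v_min >= df$v_max))
      stop("bounding boxes must satisfy u_min < u_max and v_min < v_max")
    if (any(df$confidence < 0 | df$confidence > 1))
      stop("confidences must lie in [0, 1]")
  }
  class(df) <- c("detection_records", "data.frame")
  df
}

#' Gate detections on confidence
#'
#' Keeps detections with confidence at or above the threshold (order
#' preserved). A frame whose detections all fall below threshold is marked
#' discarded: discarding is a recorded state, not an error, and discarded
#' frames get no downstream volume computed.
#'
#' @param dets A [detection_records()] data frame.
#' @param threshold Confidence threshold in `[0, 1]`; default 0.5.
#' @return A list with `kept` and `dropped` detection data frames and the
#'   flag `frame_discarded`.
#' @export
gate_detections <- function(dets, threshold = 0.5) {
  stopifnot(is.data.frame(dets))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  keep <- if (nrow(dets)) dets$confidence >= threshold else logical(0)
  list(kept = dets[keep, , drop = FALSE],
       dropped = dets[!keep, , drop = FALSE],
       frame_discarded = !any(keep))
}

#' Binary segmentation mask
#'
#' @param class_label Class name the mask belongs to.
#' @param mask Logical (or 0/1) matrix, same shape as the paired depth frame.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(class_label, mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (anyNA(mask)) stop("mask must not contain NA")
  structure(list(class_label = as.character(class_label), mask = mask),
            class = "segmentation_mask")
}

#' Label image
#'
#' An integer class-id grid plus a legend mapping every nonzero id to a
#' class label; 0 is background. The on-disk form is a paletted PNG with a
#' JSON legend sidecar (see [write_label_image()]).
#'
#' @param grid Integer matrix of class ids (0 = background).
#' @param legend Named character vector: `names` are ids, values labels.
#' @return An object of class `label_image`.
#' @export
label_image <- function(grid, legend) {
  if (!is.matrix(grid)) stop("label grid must be a matrix")
  storage.mode(grid) <- "integer"
  ids <- sort(unique(grid[grid != 0L]))
  missing <- setdiff(as.character(ids), names(legend))
  if (length(missing))
    stop(sprintf("label ids missing from legend: %s",
                 paste(missing, collapse = ", ")))
  structure(list(grid = grid, legend = legend), class = "label_image")
}

#' Split a label image into per-class binary masks
#'
#' Produces one [segmentation_mask()] per legend entry that occurs in the
#' grid; the masks are pairwise disjoint and their union is exactly the set
#' of nonzero pixels.
#'
#' @param img A [label_image()].
#' @return A list of [segmentation_mask()]s (possibly empty).
#' @export
masks_from_label_image <- function(img) {
  stopifnot(inherits(img, "label_image"))
  ids <- sort(unique(img$grid[img$grid != 0L]))
  lapply(ids, function(id)
    segmentation_mask(img$legend[[as.character(id)]], img$grid == id))
}

#' Combine masks into a label image
#'
#' Inverse of [masks_from_label_image()]; masks must be pairwise disjoint.
#'
#' @param masks List of [segmentation_mask()]s.
#' @param dims Frame dimensions `c(rows, cols)`; taken from the first mask
#'   when omitted.
#' @return A [label_image()].
#' @export
label_image_from_masks <- function(masks, dims = NULL) {
  if (!length(masks)) {
    if (is.null(dims)) stop("dims required for an empty mask list")
    return(label_image(matrix(0L, dims[1L], dims[2L]), character(0)))
  }
  if (is.null(dims)) dims <- dim(masks[[1L]]$mask)
  grid <- matrix(0L, dims[1L], dims[2L])
  legend <- character(0)
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (any(grid[m$mask] != 0L)) stop("masks overlap; cannot form label image")
    grid[m$mask] <- i
    legend[[as.character(i)]] <- m$class_label
  }
  label_image(grid, legend)
}

#' Colour-key segmentation of a rendered RGB frame
#'
#' Assigns each pixel to the class whose palette colour it matches within
#' `tol` in every channel. Intended for synthetically rendered scenes whose
#' solids carry known flat colours, giving the pipeline exact masks without
#' a trained segmentation model. Palette colours must be pairwise separated
#' by more than `2 * tol` in at least one channel, otherwise assignment
#' would be ambiguous and construction fails.
#'
#' @param rgb Numeric array `rows x cols x 3` with channels in `[0, 1]`.
#' @param palette Named list of length-3 colour vectors in `[0, 1]`.
#' @param tol Per-channel matching tolerance (default 0 = exact).
#' @return A list of [segmentation_mask()]s, one per palette class that
#'   matched at least one pixel.
#' @export
colorkey_segment <- function(rgb, palette, tol = 0) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("rgb must be a rows x cols x 3 array")
  if (tol < 0) stop("tol must be >= 0")
  labs <- names(palette)
  if (is.null(labs) || any(!nzchar(labs))) stop("palette must be named")
  if (length(palette) > 1L) {
    for (i in seq_along(palette)[-length(palette)])
      for (j in (i + 1L):length(palette)) {
        sep <- abs(unlist(palette[[i]]) - unlist(palette[[j]]))
        if (all(sep <= 2 * tol))
          stop(sprintf(
            "palette colours '%s' and '%s' are within 2*tol in every channel; ambiguous",
            labs[i], labs[j]))
      }
  }
  out <- list()
  for (lab in labs) {
    col <- unlist(palette[[lab]])
    hit <- abs(rgb[, , 1L] - col[1L]) <= tol &
      abs(rgb[, , 2L] - col[2L]) <= tol &
      abs(rgb[, , 3L] - col[3L]) <= tol
    if (any(hit)) out[[length(out) + 1L]] <- segmentation_mask(lab, hit)
  }
  out
}

#' Rasterise a polygon annotation into a mask
#'
#' Even-odd-rule rasterisation of a polygon given in continuous 0-based
#' pixel coordinates: a pixel `(u, v)` is set when its centre
#' `(u + 0.5, v + 0.5)` lies inside the polygon. Supports ingesting manually
#' traced contour annotations.
#'
#' @param vertices Two-column matrix (or list of `c(u, v)` pairs) of at
#'   least 3 polygon vertices.
#' @param shape Frame dimensions `c(rows, cols)`.
#' @param class_label Class name for the resulting mask.
#' @return A [segmentation_mask()].
#' @export
mask_from_polygon <- function(vertices, shape, class_label = "polygon") {
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stop("a polygon needs at least 3 vertices")
  if (anyNA(vertices)) stop("polygon vertices must not contain NA")
  area2 <- abs(sum(vertices[, 1L] * c(vertices[-1L, 2L], vertices[1L, 2L]) -
                     vertices[, 2L] * c(vertices[-1L, 1L], vertices[1L, 1L])))
  if (area2 == 0) stop("degenerate polygon (zero area)")
  nr <- shape[1L]; nc <- shape[2L]
  mask <- matrix(FALSE, nr, nc)
  px <- vertices[, 1L]; py <- vertices[, 2L]
  n <- nrow(vertices)
  xs <- seq_len(nc) - 0.5  # pixel-centre u coordinates
  for (row in seq_len(nr)) {
    yc <- row - 0.5
    inside <- rep(FALSE, nc)
    j <- n
    for (i in seq_len(n)) {
      yi <- py[i]; yj <- py[j]
      if ((yi > yc) != (yj > yc)) {
        xint <- px[i] + (yc - yi) / (yj - yi) * (px[j] - px[i])
        flip <- xs < xint
        inside <- xor(inside, flip)
      }
      j <- i
    }
    mask[row, ] <- inside
  }
  segmentation_mask(class_label, mask)
}
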