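# On-disk formats: 16-bit depth PNG (1 unit = 1 mm), raw float arrays with a
# JSON sidecar, paletted label PNGs with a JSON legend, polygon annotation
# JSON, detection CSV. PNG reading goes through png::readPNG; 16-bit
# grayscale writing is done by a minimal chunk writer (zlib via base R's
# memCompress) because no installed writer emits 16-bit PNG.

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- numeric(256L)
      for (i in 0:255) {
        c <- i
        for (k in 1:8)
          c <- if (c %% 2 == 1) bitwXor_dbl(3988292384, floor(c / 2))
          else floor(c / 2)
        t[i + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- 4294967295
  for (b in as.integer(bytes)) {
    idx <- bitwXor(c %% 256, b) + 1L
    c <- floor(c / 256) + 0  # shift right 8
    c <- bitwXor_dbl(c, tab[idx])
  }
  bitwXor_dbl(c, 4294967295)
}

# xor for doubles holding 32-bit unsigned values
bitwXor_dbl <- function(a, b) {
  hi_a <- floor(a / 65536); lo_a <- a %% 65536
  hi_b <- floor(b / 65536); lo_b <- b %% 65536
  bitwXor(hi_a, hi_b) * 65536 + bitwXor(lo_a, lo_b)
}

uint32_be <- function(x) {
  as.raw(c(floor(x / 16777216) %% 256, floor(x / 65536) %% 256,
           floor(x / 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(uint32_be(length(data)), body, uint32_be(crc32(body)))
}

#' Write a depth frame as 16-bit grayscale PNG
#'
#' One PNG unit = 1 mm (lossless for integer-mm depths up to 65535).
#' Invalid pixels are stored as 0, the conventional missing-depth code in
#' 16-bit depth PNGs; [read_depth_png()] maps 0 back to invalid.
#'
#' @param depth A [depth_frame()] with valid depths in (0, 65535].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_png <- function(depth, path) {
  stopifnot(inherits(depth, "depth_frame"))
  z <- round(depth$values)
  z[!depth$valid] <- 0
  if (any(z < 0 | z > 65535)) stop("depths must fit 16-bit mm units")
  if (any(z[depth$valid] == 0))
    warning("valid zero-mm depths are indistinguishable from invalid in PNG")
  nr <- nrow(z); nc <- ncol(z)
  # scanlines: filter byte 0 + big-endian 16-bit samples, row-major
  m <- t(z)  # column-major over t(z) walks row-major over z
  hi <- as.raw(floor(m / 256)); lo <- as.raw(m %% 256)
  px <- as.raw(rbind(as.integer(hi), as.integer(lo)))  # interleave hi/lo
  dim(px) <- NULL
  rows <- matrix(px, nrow = 2L * nc, ncol = nr)
  raw_img <- as.raw(rbind(rep(0L, nr), matrix(as.integer(rows), 2L * nc, nr)))
  ihdr <- c(uint32_be(nc), uint32_be(nr),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # 16-bit grayscale
  idat <- memCompress(as.raw(raw_img), type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

#' Read a 16-bit depth PNG
#'
#' @param path PNG path (16-bit grayscale, 1 unit = 1 mm).
#' @return A [depth_frame()]; stored 0 becomes invalid.
#' @export
read_depth_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  z <- round(img * 65535)
  z[z == 0] <- NA_real_
  depth_frame(z)
}

#' Write / read a depth frame as a raw float array with JSON sidecar
#'
#' Binary little-endian float64 values (row-major), with `<path>.json`
#' recording shape, units and timestamp. Readers reject sidecars whose
#' units are not `"mm"`.
#'
#' @param depth A [depth_frame()].
#' @param path Output path for the binary array (sidecar at `<path>.json`).
#' @return `path` (write) or a [depth_frame()] (read).
#' @export
write_depth_raw <- function(depth, path) {
  stopifnot(inherits(depth, "depth_frame"))
  z <- depth$values
  z[!depth$valid] <- NaN
  con <- file(path, "wb")
  writeBin(as.numeric(t(z)), con, size = 8L, endian = "little")
  close(con)
  jsonlite::write_json(
    list(shape = dim(z), units = "mm",
         timestamp = if (is.null(depth$timestamp)) NULL else depth$timestamp,
         invalid = "NaN", order = "row-major"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_depth_raw
#' @export
read_depth_raw <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$units, "mm"))
    stop(sprintf("sidecar declares units '%s'; only mm depth frames are accepted",
                 meta$units))
  n <- prod(meta$shape)
  con <- file(path, "rb")
  v <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
  close(con)
  z <- t(matrix(v, nrow = meta$shape[2L], ncol = meta$shape[1L]))
  z[is.nan(z)] <- NA_real_
  depth_frame(z, timestamp = meta$timestamp)
}

#' Write / read a label image (8-bit PNG + JSON legend sidecar)
#'
#' @param img A [label_image()] with ids in 0-255.
#' @param path PNG path; the legend goes to `<path>.json`.
#' @return `path` (write) or a [label_image()] (read).
#' @export
write_label_image <- function(img, path) {
  stopifnot(inherits(img, "label_image"))
  if (any(img$grid < 0L | img$grid > 255L)) stop("label ids must fit 8 bits")
  png::writePNG(img$grid / 255, path)
  jsonlite::write_json(as.list(img$legend), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  g <- png::readPNG(path)
  if (length(dim(g)) == 3L) g <- g[, , 1L]
  legend <- unlist(jsonlite::read_json(paste0(path, ".json"),
                                       simplifyVector = TRUE))
  if (is.null(legend)) legend <- character(0)
  label_image(matrix(as.integer(round(g * 255)), nrow(g), ncol(g)), legend)
}

#' Write an RGB frame as 8-bit PNG
#'
#' @param rgb `rows x cols x 3` array in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}

#' Read / write polygon annotations as JSON
#'
#' Records of the form `{"class": ..., "vertices": [[u, v], ...]}`,
#' ingesting manually traced object contours.
#'
#' @param path JSON path.
#' @return A list of `list(class_label, vertices)` records (read) or
#'   `path` (write).
#' @export
read_polygons_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r)
    list(class_label = r$class,
         vertices = do.call(rbind, lapply(r$vertices, unlist))))
}

#' @rdname read_polygons_json
#' @param polygons List of `list(class_label, vertices)` records.
#' @export
write_polygons_json <- function(polygons, path) {
  recs <- lapply(polygons, function(p)
    list(class = p$class_label,
         vertices = lapply(seq_len(nrow(p$vertices)),
                           function(i) as.numeric(p$vertices[i, ]))))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read detection records from CSV
#'
#' Columns: `frame_id`, `class`, `u_min`, `v_min`, `u_max`, `v_max`,
#' `confidence` and optional `timestamp`.
#'
#' @param path CSV path.
#' @return A [detection_records()] data frame with a `frame_id` column.
#' @export
read_detections_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "u_min", "v_min", "u_max", "v_max", "confidence")
  if (!all(need %in% names(df)))
    stop(sprintf("detections CSV must have columns %s",
                 paste(need, collapse = ", ")))
  out <- detection_records(df$class, df$u_min, df$v_min, df$u_max, df$v_max,
                           df$confidence,
                           timestamp = if ("timestamp" %in% names(df))
                             df$timestamp else NA_real_)
  out$frame_id <- if ("frame_id" %in% names(df)) df$frame_id else NA_character_
  out
}

#' Write a rendered bundle to disk
#'
#' Materialises a synthetic scene as files: 16-bit depth PNG, raw depth
#' array + sidecar, RGB PNG, label PNG + legend, and a ground-truth JSON
#' (analytic volumes, tray depth, kpix).
#'
#' @param bundle A `render_bundle`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem (default `"scene"`).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir, stem = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_depth_png(bundle$depth, file.path(dir, paste0(stem, "_depth.png")))
  write_depth_raw(bundle$depth, file.path(dir, paste0(stem, "_depth.f64")))
  write_rgb_png(bundle$rgb, file.path(dir, paste0(stem, "_rgb.png")))
  write_label_image(label_image_from_masks(bundle$masks,
                                           dim(bundle$depth$values)),
                    file.path(dir, paste0(stem, "_labels.png")))
  jsonlite::write_json(
    list(truth_volumes_mm3 = as.list(bundle$truth_volumes_mm3),
         tray_depth_mm = bundle$spec$tray_depth_mm, kpix = bundle$kpix),
    file.path(dir, paste0(stem, "_truth.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
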