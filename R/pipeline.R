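# End-to-end per-frame measurement and reporting: detection gating ->
# segmentation -> depth filtering/saturation -> reference point -> volume ->
# weight, with every input frame accounted for exactly once (measured,
# discarded, or errored).

#' Read a run configuration from YAML
#'
#' Expected blocks: `camera {focal_length_px, baseline_mm, width_px,
#' height_px, mount_height_mm}`, `calibration {reference_point: [u, v],
#' window, sat_min_mm, sat_max_mm, flatness_tolerance_mm}`, and optional
#' `filters`, `segmentation {tol}`, `detection_threshold`, `seed`.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  run_config(camera = do.call(camera_model, cfg$camera),
             reference_point = unlist(cfg$calibration$reference_point),
             window = cfg$calibration$window %||% 2,
             sat_min_mm = cfg$calibration$sat_min_mm,
             sat_max_mm = cfg$calibration$sat_max_mm,
             flatness_tolerance_mm = cfg$calibration$flatness_tolerance_mm %||% 10,
             filters = if (is.null(cfg$filters)) filter_config()
             else do.call(filter_config, cfg$filters),
             detection_threshold = cfg$detection_threshold %||% 0.5,
             segmentation_tol = cfg$segmentation$tol %||% 0,
             seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a run configuration
#'
#' @param camera A [camera_model()].
#' @param reference_point Length-2 `c(u, v)` 0-based tray reference pixel.
#' @param window Reference-point median half-width (px).
#' @param sat_min_mm,sat_max_mm Depth saturation band (mm).
#' @param flatness_tolerance_mm Flat-surface check tolerance (mm).
#' @param filters A [filter_config()].
#' @param detection_threshold Confidence gate in `[0, 1]` (default 0.5).
#' @param segmentation_tol Colour-key tolerance for synthetic frames.
#' @param seed Integer seed recorded in reports.
#' @return A `run_config` list.
#' @export
run_config <- function(camera, reference_point, window = 2,
                       sat_min_mm, sat_max_mm, flatness_tolerance_mm = 10,
                       filters = filter_config(), detection_threshold = 0.5,
                       segmentation_tol = 0, seed = 1L) {
  stopifnot(inherits(camera, "camera_model"),
            length(reference_point) == 2L)
  if (sat_min_mm > sat_max_mm) stop("sat_min_mm must be <= sat_max_mm")
  structure(list(camera = camera,
                 reference_point = as.integer(reference_point),
                 window = as.integer(window),
                 sat_min_mm = sat_min_mm, sat_max_mm = sat_max_mm,
                 flatness_tolerance_mm = flatness_tolerance_mm,
                 filters = filters,
                 detection_threshold = detection_threshold,
                 segmentation_tol = segmentation_tol,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the measurement pipeline over frames
#'
#' For each input frame: gate its detections at the configured confidence
#' threshold (frames whose detections all fall below it are discarded with
#' reason, not measured); obtain per-class masks (supplied masks, or
#' colour-key segmentation of the RGB frame against `palette`); optionally
#' median/spatial-filter the depth; saturate; read the reference-point
#' depth; integrate per-class volumes; and, when a weight model or density
#' table is supplied, attach weight estimates. Stage errors are recorded
#' per frame and the pipeline continues.
#'
#' @param frames A list; each element needs `depth` (a [depth_frame()]) and
#'   one of `masks` (list of [segmentation_mask()]) or `rgb` (array, used
#'   with `palette`), plus optional `detections` and `frame_id`.
#' @param config A [run_config()].
#' @param palette Optional named palette for colour-key segmentation.
#' @param weight_model Optional fitted model (`portionr_gpr`/`portionr_svr`).
#' @param densities Optional [density_table()] used when no model given.
#' @param apply_filters Run the median+spatial filter chain on each depth
#'   frame before integration (default `FALSE`: synthetic renders are
#'   already clean).
#' @return A list of class `pipeline_report`: `results` (per frame x class
#'   data frame), `discarded`, `errors`, `config`.
#' @export
run_pipeline <- function(frames, config, palette = NULL, weight_model = NULL,
                         densities = NULL, apply_filters = FALSE) {
  stopifnot(inherits(config, "run_config"))
  results <- list(); discarded <- list(); errors <- list()
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    id <- fr$frame_id %||% sprintf("frame_%03d", i)
    res <- tryCatch({
      if (!is.null(fr$detections)) {
        g <- gate_detections(fr$detections, config$detection_threshold)
        if (g$frame_discarded) {
          discarded[[length(discarded) + 1L]] <- data.frame(
            frame_id = id,
            reason = sprintf("all %d detections below confidence %.2f",
                             nrow(fr$detections), config$detection_threshold),
            stringsAsFactors = FALSE)
          next
        }
      }
      masks <- fr$masks
      if (is.null(masks)) {
        if (is.null(fr$rgb) || is.null(palette))
          stop("frame has neither masks nor rgb+palette")
        masks <- colorkey_segment(fr$rgb, palette, config$segmentation_tol)
      }
      depth <- fr$depth
      if (apply_filters) {
        depth <- apply_median_filter(depth, config$filters$median_kernel)
        depth <- apply_spatial_filter(depth, config$filters)
      }
      ref <- pick_reference_depth(depth, config$reference_point[1L],
                                  config$reference_point[2L], config$window)
      scale <- compute_kpix(config$camera, ref$depth_mm)
      vols <- compute_dish_volumes(depth, masks, ref, scale,
                                   config$sat_min_mm, config$sat_max_mm)
      rep <- volume_report(vols, frame_id = id)
      rep$weight_g <- NA_real_
      if (!is.null(weight_model)) {
        rep$weight_g <- predict(weight_model, rep$volume_mm3)
      } else if (!is.null(densities)) {
        for (r in seq_len(nrow(rep)))
          if (rep$class_label[r] %in% names(densities))
            rep$weight_g[r] <- density_weight(rep$volume_mm3[r],
                                              rep$class_label[r], densities)
      }
      rep
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- data.frame(
        frame_id = id, error = conditionMessage(res), stringsAsFactors = FALSE)
    } else if (is.data.frame(res)) {
      results[[length(results) + 1L]] <- res
    }
  }
  structure(list(
    results = if (length(results)) do.call(rbind, results)
    else volume_report(list()),
    discarded = if (length(discarded)) do.call(rbind, discarded)
    else data.frame(frame_id = character(0), reason = character(0)),
    errors = if (length(errors)) do.call(rbind, errors)
    else data.frame(frame_id = character(0), error = character(0)),
    config = config
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d measured rows, %d discarded, %d errored\n",
              nrow(x$results), nrow(x$discarded), nrow(x$errors)))
  invisible(x)
}

#' Write a pipeline report to CSV or JSON
#'
#' @param report A `pipeline_report` (or plain data frame).
#' @param path Output path; format chosen by extension (.csv / .json).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- if (inherits(report, "pipeline_report")) report$results else report
  if (grepl("\\.json$", path)) {
    obj <- if (inherits(report, "pipeline_report"))
      list(results = df, discarded = report$discarded, errors = report$errors)
    else df
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Count serving events from a detection stream
#'
#' Debounces a time-ordered stream of gated tray/plate detections:
#' consecutive detections separated by less than `gap_s` seconds merge into
#' one serving event; a gap of at least `gap_s` starts a new one. The
#' number of events is the serving count over the stream's time span. The
#' debounce embodiment (and its 5 s default gap) is this package's own
#' plumbing for the plate-counting objective; the gap is configuration.
#'
#' @param dets A [detection_records()] data frame with non-`NA`,
#'   non-decreasing `timestamp`s.
#' @param gap_s Debounce gap in seconds (default 5).
#' @param threshold Confidence gate applied first (default 0.5).
#' @return A `data.frame` of class `serving_events` with `start_s`, `end_s`,
#'   `n_detections`, `classes`.
#' @export
count_servings <- function(dets, gap_s = 5, threshold = 0.5) {
  stopifnot(is.data.frame(dets))
  if (gap_s <= 0) stop("gap_s must be > 0")
  kept <- gate_detections(dets, threshold)$kept
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_detections = integer(0), classes = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("serving_events", "data.frame")
  if (!nrow(kept)) return(empty)
  ts <- kept$timestamp
  if (anyNA(ts)) stop("serving counting requires timestamps on all detections")
  if (is.unsorted(ts)) stop("detection stream must be time-sorted")
  event <- cumsum(c(1, diff(ts) >= gap_s))
  out <- do.call(rbind, lapply(split(seq_len(nrow(kept)), event), function(ix)
    data.frame(start_s = min(ts[ix]), end_s = max(ts[ix]),
               n_detections = length(ix),
               classes = paste(sort(unique(kept$class_label[ix])),
                               collapse = ","),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("serving_events", "data.frame")
  out
}
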