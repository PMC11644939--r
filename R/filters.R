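# Depth post-processing chain: confidence gate -> median -> temporal ->
# spatial -> decimation -> saturation. Gates only remove validity; smoothers
# preserve the valid-pixel set and never manufacture validity.

#' Gate a disparity frame on stereo confidence
#'
#' Pixels whose confidence falls below the threshold are set to disparity 0
#' (the invalid sentinel); all others pass through unchanged.
#'
#' @param disp A [disparity_frame()] carrying a confidence grid.
#' @param threshold Confidence threshold in 0-255 (default 200).
#' @return A gated [disparity_frame()].
#' @export
apply_confidence_gate <- function(disp, threshold = 200) {
  stopifnot(inherits(disp, "disparity_frame"))
  if (is.null(disp$confidence))
    stop("disparity frame has no confidence grid; the gate cannot be applied")
  if (threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]")
  v <- disp$values
  v[disp$confidence < threshold] <- 0
  disparity_frame(v, disp$confidence)
}

# shift a matrix by (dr, dc), padding with NA
shift_pad <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(NA_real_, n, p)
  rs <- seq_len(n) + dr; cs <- seq_len(p) + dc
  ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= p
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Median-filter a depth frame
#'
#' Replaces each valid pixel by the median of the valid depths inside a
#' `kernel` x `kernel` window centred on it (the pixel itself included).
#' Invalid pixels are excluded from every window statistic and remain
#' invalid in the output.
#'
#' @param depth A [depth_frame()].
#' @param kernel Odd window size in pixels (default 7).
#' @return A filtered [depth_frame()].
#' @export
apply_median_filter <- function(depth, kernel = 7) {
  stopifnot(inherits(depth, "depth_frame"))
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("median kernel must be an odd integer >= 1")
  if (kernel == 1L) return(depth)
  r <- (kernel - 1L) %/% 2L
  z <- depth$values
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  stack <- vapply(seq_len(nrow(offs)),
                  function(i) shift_pad(z, offs$dr[i], offs$dc[i]),
                  z)
  dim(stack) <- c(nrow(z) * ncol(z), nrow(offs))
  med <- apply(stack, 1L, stats::median, na.rm = TRUE)
  out <- matrix(med, nrow(z), ncol(z))
  out[!depth$valid] <- NA_real_
  depth_frame(out, depth$valid, depth$timestamp)
}

#' Temporally stabilise a sequence of depth frames
#'
#' Per-pixel exponential moving average across time:
#' `out_t = alpha * in_t + (1 - alpha) * out_{t-1}`, with `out_0 = in_0`.
#' A pixel that is invalid at time `t` passes the previous filter state
#' through (hold-last-value); a pixel with no valid history stays invalid.
#'
#' @param frames A list of [depth_frame()]s, all the same shape.
#' @param alpha EMA coefficient in (0, 1]; `alpha = 1` reproduces the input.
#' @return A list of [depth_frame()]s of the same length.
#' @export
apply_temporal_filter <- function(frames, alpha = 0.1) {
  if (length(frames) < 1L) stop("need at least one frame")
  stopifnot(all(vapply(frames, inherits, TRUE, "depth_frame")))
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  dims <- dim(frames[[1L]]$values)
  state <- matrix(NA_real_, dims[1L], dims[2L])
  state_valid <- matrix(FALSE, dims[1L], dims[2L])
  out <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    f <- frames[[t]]
    if (!identical(dim(f$values), dims))
      stop(sprintf("frame %d shape %d x %d differs from first frame %d x %d",
                   t, nrow(f$values), ncol(f$values), dims[1L], dims[2L]))
    fresh <- f$valid & !state_valid
    both <- f$valid & state_valid
    state[fresh] <- f$values[fresh]
    state[both] <- alpha * f$values[both] + (1 - alpha) * state[both]
    state_valid <- state_valid | f$valid
    out[[t]] <- depth_frame(ifelse(state_valid, state, NA_real_),
                            state_valid, f$timestamp)
  }
  out
}

# One directional smoothing pass along rows of `z`. For output pixel i the
# neighbours j with |j - i| <= radius contribute with weight
# (1 - alpha)^|j - i|, excluding invalid neighbours and, when delta > 0,
# neighbours whose depth differs from the centre pixel by more than delta
# (the edge-preservation rule). Weights are renormalised per pixel.
smooth_pass_rows <- function(z, valid, alpha, radius, delta) {
  num <- ifelse(valid, z, 0)
  den <- matrix(as.numeric(valid), nrow(z), ncol(z))
  if (radius >= 1L) {
    for (s in c(-(radius:1), 1:radius)) {
      w <- (1 - alpha)^abs(s)
      if (w == 0) next
      zs <- shift_pad(z, 0L, s)
      ok <- !is.na(zs)
      if (delta > 0) ok <- ok & !is.na(z) & abs(zs - z) <= delta
      num <- num + w * ifelse(ok, zs, 0)
      den <- den + w * ok
    }
  }
  out <- ifelse(valid & den > 0, num / den, NA_real_)
  out
}

#' Edge-aware spatial smoothing of a depth frame
#'
#' Runs `spatial_iterations` passes of a horizontal-then-vertical windowed
#' exponential smoother. Within `spatial_radius` pixels, neighbours are
#' weighted by `(1 - spatial_alpha)^distance`; when `spatial_delta > 0`,
#' neighbours whose depth differs from the centre pixel by more than
#' `spatial_delta` mm are excluded, preserving edges. `spatial_delta = 0`
#' means no edge threshold (pure smoothing), and `spatial_alpha = 1` leaves
#' the frame unchanged. Invalid pixels neither contribute nor gain validity.
#'
#' @param depth A [depth_frame()].
#' @param cfg A [filter_config()] supplying alpha/radius/delta/iterations.
#' @return A smoothed [depth_frame()].
#' @export
apply_spatial_filter <- function(depth, cfg = filter_config()) {
  stopifnot(inherits(depth, "depth_frame"), inherits(cfg, "filter_config"))
  z <- depth$values
  for (it in seq_len(cfg$spatial_iterations)) {
    z <- smooth_pass_rows(z, depth$valid, cfg$spatial_alpha,
                          cfg$spatial_radius, cfg$spatial_delta)
    z <- t(smooth_pass_rows(t(z), t(depth$valid), cfg$spatial_alpha,
                            cfg$spatial_radius, cfg$spatial_delta))
  }
  z[!depth$valid] <- NA_real_
  depth_frame(z, depth$valid, depth$timestamp)
}

#' Decimate a depth-frame stream
#'
#' Temporal mode (the default, matching "half of the images are considered"
#' at factor 2) keeps every `factor`-th frame starting at the first. Spatial
#' mode instead subsamples every `factor`-th row and column of each frame.
#'
#' @param frames A list of [depth_frame()]s.
#' @param factor Integer >= 1.
#' @param mode `"temporal"` (default) or `"spatial"`.
#' @return A list of [depth_frame()]s.
#' @export
decimate_stream <- function(frames, factor = 2, mode = c("temporal", "spatial")) {
  mode <- match.arg(mode)
  factor <- as.integer(factor)
  if (factor < 1L) stop("decimation factor must be >= 1")
  if (mode == "temporal") return(frames[seq(1L, length(frames), by = factor)])
  lapply(frames, function(f) {
    rs <- seq(1L, nrow(f$values), by = factor)
    cs <- seq(1L, ncol(f$values), by = factor)
    depth_frame(f$values[rs, cs, drop = FALSE],
                f$valid[rs, cs, drop = FALSE], f$timestamp)
  })
}

#' Saturate a depth frame to a band
#'
#' Clamps every valid depth into `[sat_min, sat_max]` mm; validity is
#' preserved. Applied before volume integration so out-of-band returns
#' (reflections, occasional speckle) cannot dominate the height sums.
#'
#' @param depth A [depth_frame()].
#' @param sat_min,sat_max Saturation band in mm, `sat_min <= sat_max`.
#' @return A clamped [depth_frame()].
#' @export
saturate_depth <- function(depth, sat_min, sat_max) {
  stopifnot(inherits(depth, "depth_frame"))
  if (sat_min > sat_max) stop("sat_min must be <= sat_max")
  z <- pmin(pmax(depth$values, sat_min), sat_max)
  depth_frame(z, depth$valid, depth$timestamp)
}
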