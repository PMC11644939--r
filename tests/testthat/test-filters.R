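# Loop-based reference implementations used as oracles ------------------

median_oracle <- function(z, kernel) {
  r <- (kernel - 1) %/% 2
  out <- z
  for (i in seq_len(nrow(z))) for (j in seq_len(ncol(z))) {
    if (is.na(z[i, j])) next
    win <- z[max(1, i - r):min(nrow(z), i + r),
             max(1, j - r):min(ncol(z), j + r)]
    out[i, j] <- median(win[!is.na(win)])
  }
  out
}

spatial_oracle_pass <- function(z, alpha, radius, delta) {
  # one horizontal followed by one vertical windowed pass
  pass1d <- function(vec) {
    out <- vec
    for (i in seq_along(vec)) {
      if (is.na(vec[i])) next
      num <- 0; den <- 0
      for (j in max(1, i - radius):min(length(vec), i + radius)) {
        if (is.na(vec[j])) next
        if (delta > 0 && abs(vec[j] - vec[i]) > delta) next
        w <- (1 - alpha)^abs(j - i)
        num <- num + w * vec[j]; den <- den + w
      }
      out[i] <- num / den
    }
    out
  }
  z <- t(apply(z, 1, pass1d))
  apply(z, 2, pass1d)
}

test_that("confidence gate invalidates exactly the sub-threshold pixels", {
  set.seed(11)
  vals <- matrix(runif(48, 1, 50), 6, 8)
  conf <- matrix(sample(0:255, 48, replace = TRUE), 6, 8)
  d <- disparity_frame(vals, conf)
  expect_identical(apply_confidence_gate(d, 200)$values,
                   ifelse(conf < 200, 0, vals))
  # all confident -> unchanged; none confident -> all invalid
  expect_identical(
    apply_confidence_gate(disparity_frame(vals, matrix(255L, 6, 8)), 200)$values,
    vals)
  expect_true(all(
    apply_confidence_gate(disparity_frame(vals, matrix(0L, 6, 8)), 200)$values == 0))
  expect_error(apply_confidence_gate(disparity_frame(vals), 200), "confidence")
})

test_that("median filter removes spikes and matches the sliding-window oracle", {
  flat <- flat_depth(12, 12, 1000)
  expect_equal(apply_median_filter(flat, 7)$values, flat$values)

  spike <- flat$values; spike[6, 6] <- 1500
  out <- apply_median_filter(depth_frame(spike), 7)
  expect_equal(out$values[6, 6], 1000)

  expect_error(apply_median_filter(flat, 4), "odd")

  for (seed in 1:8) {
    d <- random_depth(9, 9, seed, invalid_frac = 0.1)
    got <- apply_median_filter(d, 3)
    expect_equal(got$values, median_oracle(d$values, 3))
    expect_identical(got$valid, d$valid)  # no validity manufactured
  }
})

test_that("temporal EMA matches its closed form and stays a convex combination", {
  frames <- replicate(5, flat_depth(4, 4, 900), simplify = FALSE)
  out <- apply_temporal_filter(frames, 0.1)
  for (f in out) expect_equal(f$values, frames[[1]]$values)

  # alpha = 1 reproduces the input
  set.seed(3)
  seq_in <- lapply(1:4, function(i) random_depth(5, 5, i))
  out1 <- apply_temporal_filter(seq_in, 1)
  for (i in 1:4) expect_equal(out1[[i]]$values, seq_in[[i]]$values)

  # step input: geometric approach to the new level, term by term
  alpha <- 0.1
  step <- c(lapply(1:3, function(i) flat_depth(3, 3, 1000)),
            lapply(1:6, function(i) flat_depth(3, 3, 1100)))
  outs <- apply_temporal_filter(step, alpha)
  for (t in 1:6) {
    expected <- 1100 - (1100 - 1000) * (1 - alpha)^t
    expect_equal(outs[[3 + t]]$values[1, 1], expected, tolerance = 1e-12)
  }

  # convex combination: per-pixel output bounded by the inputs seen so far
  set.seed(9)
  seq2 <- lapply(1:6, function(i) random_depth(6, 6, i + 100))
  out2 <- apply_temporal_filter(seq2, 0.3)
  stack <- simplify2array(lapply(seq2, function(f) f$values))
  for (t in 1:6) {
    lo <- apply(stack[, , 1:t, drop = FALSE], c(1, 2), min)
    hi <- apply(stack[, , 1:t, drop = FALSE], c(1, 2), max)
    expect_true(all(out2[[t]]$values >= lo - 1e-12 &
                      out2[[t]]$values <= hi + 1e-12))
  }

  # invalid pixels pass the previous state through
  a <- flat_depth(2, 2, 1000)
  bvals <- matrix(c(NA, 1200, 1200, 1200), 2, 2)
  outh <- apply_temporal_filter(list(a, depth_frame(bvals)), 0.5)
  expect_equal(outh[[2]]$values[1, 1], 1000)

  expect_error(apply_temporal_filter(list(a, flat_depth(3, 3, 1)), 0.5),
               "shape")
})

test_that("spatial filter is idempotent on constants and matches the loop oracle", {
  flat <- flat_depth(10, 10, 1234)
  cfg <- filter_config(spatial_alpha = 0.1, spatial_radius = 2,
                       spatial_delta = 0, spatial_iterations = 4)
  expect_equal(apply_spatial_filter(flat, cfg)$values, flat$values)

  d <- random_depth(10, 10, 5)
  cfg1 <- filter_config(spatial_alpha = 1, spatial_iterations = 4)
  expect_equal(apply_spatial_filter(d, cfg1)$values, d$values)

  # aggregate deviation from a noisy plane is reduced
  set.seed(21)
  plane <- matrix(1000, 15, 15)
  noisy <- depth_frame(plane + matrix(rnorm(225, 0, 5), 15, 15))
  sm <- apply_spatial_filter(noisy, cfg)
  expect_lt(mean(abs(sm$values - plane)), mean(abs(noisy$values - plane)))

  # oracle agreement, including edge threshold and invalid pixels
  for (seed in 1:6) {
    dd <- random_depth(8, 8, seed + 40, invalid_frac = 0.1)
    for (delta in c(0, 30)) {
      cfg2 <- filter_config(spatial_alpha = 0.2, spatial_radius = 2,
                            spatial_delta = delta, spatial_iterations = 1)
      got <- apply_spatial_filter(dd, cfg2)
      want <- spatial_oracle_pass(dd$values, 0.2, 2, delta)
      want[!dd$valid] <- NA
      expect_equal(got$values, want, tolerance = 1e-12)
    }
  }
})

test_that("stream decimation keeps every factor-th frame", {
  frames <- lapply(1:10, function(i) flat_depth(2, 2, 1000 + i))
  kept <- decimate_stream(frames, 2)
  expect_equal(vapply(kept, function(f) f$values[1, 1], 1),
               c(1001, 1003, 1005, 1007, 1009))
  expect_identical(decimate_stream(frames, 1), frames)
  expect_length(decimate_stream(frames[1], 2), 1L)
  expect_error(decimate_stream(frames, 0), ">= 1")
  # spatial mode subsamples the pixel grid instead
  sp <- decimate_stream(list(flat_depth(6, 8, 1)), 2, mode = "spatial")
  expect_equal(dim(sp[[1]]$values), c(3, 4))
})

test_that("saturation clamps into the band and preserves validity", {
  z <- depth_frame(matrix(c(5000, 100, 700, NA), 2, 2))
  out <- saturate_depth(z, 300, 1500)
  expect_equal(out$values[1, 1], 1500)
  expect_equal(out$values[2, 1], 300)
  expect_equal(out$values[1, 2], 700)
  expect_true(is.na(out$values[2, 2]))
  expect_identical(out$valid, z$valid)
  expect_true(all(out$values[out$valid] >= 300 & out$values[out$valid] <= 1500))
  expect_error(saturate_depth(z, 1500, 300), "sat_min")
})
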