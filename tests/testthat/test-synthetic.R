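test_that("empty scenes render as a constant tray plane", {
  cam <- camera_model(600, 75, 40, 30, mount_height_mm = 1200)
  b <- render_scene(scene_spec(cam, 1200))
  expect_true(all(b$depth$values == 1200))
  expect_length(b$masks, 0L)
  expect_equal(b$kpix, 2)
})

test_that("rendered solids carry exact masks and analytic truth volumes", {
  cub <- solid_spec("cuboid", x_mm = 50, y_mm = 40, height = 20,
                    class_label = "block")
  b <- render_scene(solid_scene(cub))
  expect_equal(unname(b$truth_volumes_mm3["block"]), 40000)
  v <- measure_bundle(b)[[1]]$volume_mm3
  expect_lt(abs(v - 40000) / 40000, 0.01)

  cap <- solid_spec("spherical_cap", R = 60, h = 40, class_label = "cap")
  expect_equal(analytic_volume(cap), pi * 40^2 * (3 * 60 - 40) / 3)
  fr <- solid_spec("frustum", r_base = 50, r_top = 30, height = 35,
                   class_label = "fr")
  expect_equal(analytic_volume(fr), pi * 35 * (2500 + 1500 + 900) / 3)

  expect_error(
    scene_spec(camera_model(2400, 75, 320, 320), 1200,
               list(solid_spec("cylinder", radius = 40, height = 10),
                    solid_spec("cylinder", radius = 40, height = 10,
                               center = c(50, 0), class_label = "b"))),
    "overlap")
  # a footprint that would be clipped by the frame edge is refused
  expect_error(
    scene_spec(camera_model(2400, 75, 320, 320), 1200,
               list(solid_spec("cylinder", radius = 40, height = 10,
                               center = c(60, 0)))),
    "beyond")
})

test_that("a zero noise spec leaves the bundle bit-identical", {
  cap <- solid_spec("spherical_cap", R = 50, h = 30, class_label = "cap")
  b <- render_scene(solid_scene(cap, npx = 240))
  b2 <- apply_stereo_noise(b, noise_spec())
  expect_identical(b2$depth$values, b$depth$values)
})

test_that("disparity quantization error follows the closed form fB/d vs fB/(d+-q)", {
  cam <- camera_model(2400, 75, 40, 40, mount_height_mm = 1200)
  fB <- 2400 * 75
  q <- 1 / 8
  for (z0 in c(600, 1200)) {
    z <- z0 + 3.137  # off the quantization grid
    b <- render_scene(scene_spec(cam, z))
    bn <- apply_stereo_noise(b, noise_spec(disparity_quantization_px = q))
    err <- max(abs(bn$depth$values - z))
    closed_form <- abs(fB / (round((fB / z) / q) * q) - z)
    expect_equal(err, closed_form, tolerance = 1e-9)
    # and never beyond the worst-case half-step bound
    expect_lte(err, abs(fB / (fB / z - q / 2) - z) + 1e-9)
  }
  # the worst-case bound grows quadratically with depth
  bound <- function(z) abs(fB / (fB / z - q / 2) - z)
  expect_equal(bound(1200) / bound(600), 4, tolerance = 0.05)

  # finer quantization gives smaller volume error
  cap <- solid_spec("spherical_cap", R = 60, h = 40, class_label = "cap")
  sc <- solid_scene(cap)
  b <- render_scene(sc)
  va <- analytic_volume(cap)
  verr <- vapply(c(1 / 2, 1 / 8), function(qq) {
    bn <- apply_stereo_noise(b, noise_spec(disparity_quantization_px = qq))
    abs(measure_bundle(bn)[[1]]$volume_mm3 - va)
  }, numeric(1))
  expect_lt(verr[2], verr[1])
})

test_that("stereo noise is reproducible under its seed", {
  cap <- solid_spec("spherical_cap", R = 50, h = 30, class_label = "cap")
  b <- render_scene(solid_scene(cap, npx = 240))
  ns <- noise_spec(disparity_quantization_px = 1 / 8,
                   gaussian_depth_sigma_mm = 2, seed = 99)
  b1 <- apply_stereo_noise(b, ns)
  b2 <- apply_stereo_noise(b, ns)
  expect_identical(b1$depth$values, b2$depth$values)
  b3 <- apply_stereo_noise(b, noise_spec(disparity_quantization_px = 1 / 8,
                                         gaussian_depth_sigma_mm = 2,
                                         seed = 100))
  expect_false(identical(b3$depth$values, b1$depth$values))
})

test_that("dropout regions invalidate or flatten as configured", {
  cap <- solid_spec("spherical_cap", R = 60, h = 40, class_label = "cap")
  b <- render_scene(solid_scene(cap))
  # invalid mode removes pixels and the volume stage reports them
  inv <- apply_stereo_noise(b, noise_spec(dropout_regions = list(
    list(region = list(type = "rect", u0 = 150, v0 = 150, u1 = 170, v1 = 170),
         mode = "invalid"))))
  expect_lt(mean(inv$depth$valid), 1)
  res <- measure_bundle(inv)[[1]]
  expect_gt(res$invalid_in_mask_count, 0)

  # flattening the low-texture top pins its depth and loses volume
  flat <- apply_stereo_noise(b, noise_spec(dropout_regions = list(
    list(region = list(type = "class_top", class_label = "cap",
                       min_height_mm = 25),
         mode = list(flatten_to = 1200 - 25)))))
  expect_lt(measure_bundle(flat)[[1]]$volume_mm3,
            measure_bundle(b)[[1]]$volume_mm3)
})

test_that("weight datasets follow their recorded law and seed", {
  d <- generate_weight_dataset(24, list(type = "linear", slope = 0.0008),
                               0, seed = 8)
  f <- attr(d, "true_law")
  expect_equal(d$weight_g, f(d$volume_mm3))
  expect_equal(d$weight_g, 0.0008 * d$volume_mm3)

  d2 <- generate_weight_dataset(24, list(type = "linear", slope = 0.0008),
                                0, seed = 8)
  expect_identical(d2$volume_mm3, d$volume_mm3)

  ds <- generate_weight_dataset(40, list(type = "sigmoid"), 8, seed = 3)
  fs <- attr(ds, "true_law")
  resid <- ds$weight_g - fs(ds$volume_mm3)
  expect_lt(abs(sd(resid) - 8), 3)
  expect_error(generate_weight_dataset(3, list(type = "linear")), "n >= 4")
})
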