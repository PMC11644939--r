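test_that("surface contribution is RP - depth_sat inside the mask, clamped at 0", {
  z <- depth_frame(matrix(c(1150, 1200, 1250, NA), 2, 2))
  mask <- segmentation_mask("food", matrix(TRUE, 2, 2))
  scale <- compute_kpix(camera_model(400, 75, 2, 2), 1200)
  s <- surface_contribution(z, mask, 1200, scale)
  expect_equal(s$sup[1, 1], 50)   # food above tray
  expect_equal(s$sup[2, 1], 0)    # at tray level
  expect_equal(s$sup[1, 2], 0)    # below plane: clamped
  expect_equal(s$clamped_negative_count, 1L)
  expect_equal(s$invalid_in_mask_count, 1L)
  expect_equal(s$sup[2, 2], 0)    # invalid contributes zero
  expect_true(all(s$sup >= 0))

  # outside the mask the contribution is identically zero
  half <- matrix(FALSE, 2, 2); half[1, 1] <- TRUE
  s2 <- surface_contribution(z, segmentation_mask("food", half), 1200, scale)
  expect_equal(s2$sup[2, 1], 0)
  expect_equal(s2$pixel_count, 1L)

  expect_error(
    surface_contribution(z, segmentation_mask("food", matrix(TRUE, 3, 3)),
                         1200, scale),
    "shapes differ")
})

test_that("volume integration matches its closed form and a loop oracle", {
  cam <- camera_model(400, 75, 120, 100)
  scale <- pixel_scale(0.5, 200)
  # uniform 100 x 80 block of 20 mm height at kpix 0.5
  z <- matrix(1200, 100, 120)
  mask <- matrix(FALSE, 100, 120); mask[1:100, 1:80] <- TRUE
  z[mask] <- 1180
  s <- surface_contribution(depth_frame(z), segmentation_mask("block", mask),
                            1200, scale)
  expect_equal(integrate_volume(s)$volume_mm3, 100 * 80 * 20 * 0.25)

  # empty mask integrates to zero
  s0 <- surface_contribution(flat_depth(10, 10),
                             segmentation_mask("none", matrix(FALSE, 10, 10)),
                             1200, scale)
  expect_equal(integrate_volume(s0)$volume_mm3, 0)

  # random surface vs per-pixel accumulation
  for (seed in 1:5) {
    d <- random_depth(12, 12, seed, base = 1100, spread = 80)
    m <- matrix(runif(144) < 0.5, 12, 12)
    sr <- surface_contribution(d, segmentation_mask("r", m), 1150, scale)
    acc <- 0
    for (i in 1:12) for (j in 1:12)
      if (m[i, j] && !is.na(d$values[i, j]))
        acc <- acc + max(1150 - d$values[i, j], 0) * 0.25
    expect_equal(integrate_volume(sr)$volume_mm3, acc, tolerance = 1e-12)
  }
})

test_that("volume scales linearly in height and quadratically in kpix", {
  d <- random_depth(15, 15, 3, base = 1100, spread = 40)
  m <- segmentation_mask("x", matrix(TRUE, 15, 15))
  mk_scale <- function(k) pixel_scale(k, 1200)
  v1 <- integrate_volume(surface_contribution(d, m, 1200, mk_scale(0.5)))
  # doubling every height via a doubled reference offset
  d2 <- depth_frame(1200 - 2 * (1200 - d$values))
  v2 <- integrate_volume(surface_contribution(d2, m, 1200, mk_scale(0.5)))
  expect_equal(v2$volume_mm3, 2 * v1$volume_mm3, tolerance = 1e-10)
  v3 <- integrate_volume(surface_contribution(d, m, 1200, mk_scale(1.0)))
  expect_equal(v3$volume_mm3, 4 * v1$volume_mm3, tolerance = 1e-10)
})

test_that("dish volumes recover analytic solids and are mask-additive", {
  cap <- solid_spec("spherical_cap", R = 60, h = 40, class_label = "cap")
  b <- render_scene(solid_scene(cap))
  v <- measure_bundle(b)[[1]]$volume_mm3
  va <- pi * 40^2 * (3 * 60 - 40) / 3
  expect_lt(abs(v - va) / va, 0.02)

  # flat tray: zero volume for any mask
  empty <- render_scene(scene_spec(camera_model(2400, 75, 64, 64), 1200))
  rp <- pick_reference_depth(empty$depth, 5, 5, 2)
  sc <- compute_kpix(empty$spec$camera, rp$depth_mm)
  vol0 <- compute_dish_volumes(empty$depth,
                               list(segmentation_mask("any",
                                                      matrix(TRUE, 64, 64))),
                               rp, sc, 300, 1500)
  expect_equal(vol0[[1]]$volume_mm3, 0)

  # two disjoint solids measure the same as their single-solid scenes
  cyl <- solid_spec("cylinder", radius = 30, height = 25,
                    class_label = "cyl", center = c(95, 0),
                    color = c(0, 0, 1))
  cap2 <- solid_spec("spherical_cap", R = 50, h = 30, class_label = "cap",
                     center = c(-70, 0))
  cam <- camera_model(2400, 75, 560, 320)
  both <- render_scene(scene_spec(cam, 1200, list(cap2, cyl)))
  vols_both <- measure_bundle(both)
  one <- render_scene(scene_spec(cam, 1200, list(cap2)))
  two <- render_scene(scene_spec(cam, 1200, list(cyl)))
  expect_equal(vols_both[[1]]$volume_mm3, measure_bundle(one)[[1]]$volume_mm3,
               tolerance = 1e-10)
  expect_equal(vols_both[[2]]$volume_mm3, measure_bundle(two)[[1]]$volume_mm3,
               tolerance = 1e-10)
})

test_that("height mesh mirrors the surface grid at kpix spacing", {
  scale <- pixel_scale(0.5, 1200)
  z <- depth_frame(matrix(c(1190, 1200, 1195, 1200), 2, 2))
  s <- surface_contribution(z, segmentation_mask("m", matrix(TRUE, 2, 2)),
                            1200, scale)
  mesh <- build_mesh(s)
  expect_equal(nrow(mesh$vertices), 4L)
  expect_equal(nrow(mesh$faces), 2L)
  expect_equal(sort(unique(mesh$vertices[, 1])), c(0, 0.5))
  expect_equal(mesh$vertices[, 3], as.vector(s$sup))
  expect_equal(mesh$view, "top")

  # flat surface -> planar mesh at z = 0
  s0 <- surface_contribution(flat_depth(3, 3),
                             segmentation_mask("m", matrix(TRUE, 3, 3)),
                             1200, scale)
  expect_true(all(build_mesh(s0)$vertices[, 3] == 0))

  # exports are parseable text/binary with the right counts
  obj <- tempfile(fileext = ".obj")
  write_mesh_obj(mesh, obj)
  lines <- readLines(obj)
  expect_equal(sum(startsWith(lines, "v ")), 4L)
  expect_equal(sum(startsWith(lines, "f ")), 2L)
  ply <- tempfile(fileext = ".ply")
  write_mesh_ply(mesh, ply)
  expect_match(readLines(ply, n = 2, warn = FALSE)[2], "binary_little_endian")
})

test_that("voxel oracle converges to analytic volumes", {
  cube <- solid_spec("cuboid", x_mm = 10, y_mm = 10, height = 10,
                     class_label = "cube")
  expect_equal(voxel_volume_oracle(cube, 1), 1000)

  cap <- solid_spec("spherical_cap", R = 20, h = 12, class_label = "cap")
  va <- analytic_volume(cap)
  v1 <- voxel_volume_oracle(cap, 1)
  v05 <- voxel_volume_oracle(cap, 0.5)
  v025 <- voxel_volume_oracle(cap, 0.25)
  expect_lt(abs(v025 - va) / va, 0.01)
  # monotone refinement on a convex solid
  expect_lte(abs(v05 - va), abs(v1 - va))
  expect_lte(abs(v025 - va), abs(v05 - va))
  expect_error(voxel_volume_oracle(cap, 0), "> 0")
})
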