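polygon_oracle <- function(vertices, shape) {
  # per-pixel even-odd ray-casting, scalar loop
  inside_pt <- function(x, y) {
    n <- nrow(vertices); cnt <- 0; j <- n
    for (i in seq_len(n)) {
      xi <- vertices[i, 1]; yi <- vertices[i, 2]
      xj <- vertices[j, 1]; yj <- vertices[j, 2]
      if ((yi > y) != (yj > y) &&
          x < xi + (y - yi) / (yj - yi) * (xj - xi)) cnt <- cnt + 1
      j <- i
    }
    cnt %% 2 == 1
  }
  m <- matrix(FALSE, shape[1], shape[2])
  for (v in seq_len(shape[1])) for (u in seq_len(shape[2]))
    m[v, u] <- inside_pt(u - 0.5, v - 0.5)
  m
}

test_that("confidence gating keeps order, records discards, and is monotone", {
  dets <- detection_records(c("chicken", "rice"), c(0, 50), c(0, 50),
                            c(40, 90), c(40, 90), c(0.9, 0.4))
  g <- gate_detections(dets, 0.5)
  expect_equal(nrow(g$kept), 1L)
  expect_equal(g$kept$class_label, "chicken")
  expect_false(g$frame_discarded)

  empty <- detection_records(character(0), numeric(0), numeric(0),
                             numeric(0), numeric(0), numeric(0))
  ge <- gate_detections(empty, 0.5)
  expect_equal(nrow(ge$kept), 0L)
  expect_true(ge$frame_discarded)

  all_in <- gate_detections(dets, 0.2)
  expect_equal(all_in$kept$class_label, c("chicken", "rice"))

  # monotone: raising the threshold never adds detections
  set.seed(17)
  many <- detection_records(letters[1:30], 0, 0, 10, 10, runif(30))
  prev <- nrow(many)
  for (thr in seq(0, 1, by = 0.1)) {
    k <- nrow(gate_detections(many, thr)$kept)
    expect_lte(k, prev)
    prev <- k
  }
})

test_that("label images split into disjoint masks and round-trip", {
  grid <- matrix(0L, 8, 8)
  grid[2:4, 2:4] <- 1L
  grid[6:7, 5:8] <- 2L
  img <- label_image(grid, c(`1` = "rice", `2` = "chicken"))
  masks <- masks_from_label_image(img)
  expect_length(masks, 2L)
  expect_false(any(masks[[1]]$mask & masks[[2]]$mask))
  expect_equal(masks[[1]]$mask | masks[[2]]$mask, grid != 0L)
  # pixel counts equal the id histogram
  expect_equal(sum(masks[[1]]$mask), sum(grid == 1L))
  expect_equal(sum(masks[[2]]$mask), sum(grid == 2L))
  # round trip
  back <- label_image_from_masks(masks, dim(grid))
  masks2 <- masks_from_label_image(back)
  for (i in 1:2) {
    expect_identical(masks2[[i]]$mask, masks[[i]]$mask)
    expect_identical(masks2[[i]]$class_label, masks[[i]]$class_label)
  }

  expect_length(masks_from_label_image(
    label_image(matrix(0L, 4, 4), character(0))), 0L)
  expect_error(label_image(grid, c(`1` = "rice")), "missing from legend")
})

test_that("colour-key segmentation reproduces ground-truth masks", {
  cap <- solid_spec("spherical_cap", R = 40, h = 25, class_label = "rice",
                    color = c(0.9, 0.9, 0.2), center = c(-40, 0))
  cyl <- solid_spec("cylinder", radius = 25, height = 25,
                    class_label = "chicken", color = c(0.6, 0.3, 0.1),
                    center = c(42, 0))
  b <- render_scene(scene_spec(camera_model(600, 75, 160, 120,
                                            mount_height_mm = 600),
                               solids = list(cap, cyl)))
  segs <- colorkey_segment(b$rgb, scene_palette(b$spec), tol = 0)
  expect_length(segs, 2L)
  for (i in 1:2) expect_identical(segs[[i]]$mask, b$masks[[i]]$mask)

  # with sub-tolerance noise the masks still match exactly
  set.seed(23)
  noisy <- b$rgb + array(runif(length(b$rgb), -0.02, 0.02), dim(b$rgb))
  segs2 <- colorkey_segment(noisy, scene_palette(b$spec), tol = 0.05)
  for (i in 1:2) expect_identical(segs2[[i]]$mask, b$masks[[i]]$mask)

  # uniform background yields no masks
  bg <- array(0.5, dim = c(10, 10, 3))
  expect_length(colorkey_segment(bg, list(rice = c(1, 1, 0)), 0.1), 0L)

  expect_error(
    colorkey_segment(bg, list(a = c(0.5, 0.5, 0.5), b = c(0.52, 0.52, 0.52)),
                     tol = 0.05),
    "ambiguous")
})

test_that("polygon rasterisation follows the even-odd rule at pixel centres", {
  # axis-aligned rectangle: interior pixel count is width x height
  rect <- rbind(c(2, 3), c(12, 3), c(12, 8), c(2, 8))
  m <- mask_from_polygon(rect, c(20, 20))
  expect_equal(sum(m$mask), 10 * 5)

  # triangle and star-ish polygons vs the brute-force oracle
  tri <- rbind(c(1, 1), c(18, 4), c(6, 17))
  expect_identical(mask_from_polygon(tri, c(20, 20))$mask,
                   polygon_oracle(tri, c(20, 20)))
  for (seed in 1:10) {
    set.seed(seed)
    poly <- cbind(runif(7, 0, 20), runif(7, 0, 20))
    expect_identical(mask_from_polygon(poly, c(20, 20))$mask,
                     polygon_oracle(poly, c(20, 20)))
  }

  # polygon entirely outside the frame rasterises to an empty mask
  out <- mask_from_polygon(rbind(c(30, 30), c(40, 30), c(35, 40)), c(20, 20))
  expect_equal(sum(out$mask), 0)

  expect_error(mask_from_polygon(rbind(c(1, 1), c(2, 2)), c(10, 10)),
               "at least 3")
  expect_error(mask_from_polygon(rbind(c(1, 1), c(2, 2), c(3, 3)), c(10, 10)),
               "degenerate")
})
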