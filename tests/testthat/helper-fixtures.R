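# Shared fixture builders. Everything is generated in code; seeds are fixed
# per call site.

flat_depth <- function(nr, nc, depth_mm = 1200) {
  depth_frame(matrix(depth_mm, nr, nc))
}

random_depth <- function(nr, nc, seed, base = 1200, spread = 50,
                         invalid_frac = 0) {
  set.seed(seed)
  z <- matrix(base + runif(nr * nc, -spread, spread), nr, nc)
  if (invalid_frac > 0)
    z[sample(nr * nc, round(invalid_frac * nr * nc))] <- NA_real_
  depth_frame(z)
}

# standard single-solid test scene at kpix = 0.5 mm/px
solid_scene <- function(solid, tray = 1200, npx = 320) {
  cam <- camera_model(focal_length_px = tray / 0.5, baseline_mm = 75,
                      width_px = npx, height_px = npx, mount_height_mm = tray)
  scene_spec(cam, tray_depth_mm = tray, solids = list(solid))
}

# run the measurement chain on a rendered bundle with ground-truth masks
measure_bundle <- function(bundle, ref_uv = c(6, 6), sat = c(300, 1500)) {
  rp <- pick_reference_depth(bundle$depth, ref_uv[1], ref_uv[2], 2)
  scale <- compute_kpix(bundle$spec$camera, rp$depth_mm)
  compute_dish_volumes(bundle$depth, bundle$masks, rp, scale, sat[1], sat[2])
}

# draw one replicate of (train, test) data from an OU GP + iid noise,
# mapped onto plausible volume/weight scales for the fitting interface
sim_gp_replicate <- function(seed, domain, l, sf2, sn, ntr, nte) {
  set.seed(seed)
  n <- ntr + nte
  x <- sort(runif(n, 0, domain))
  p <- exp_gpr_params(sf2, l, sn^2)
  K <- kernel_exponential(x, x, p, "ou")
  f <- drop(t(chol(K + diag(1e-8, n))) %*% rnorm(n))
  y <- f + rnorm(n, 0, sn)
  te <- sort(sample(n, nte))
  tr <- setdiff(seq_len(n), te)
  list(train = volume_weight_set(x[tr] * 1e4 + 1, y[tr] + 100),
       test_volume = x[te] * 1e4 + 1,
       test_weight = y[te] + 100,
       x_unit = 1e4)
}
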