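test_that("FRET index follows the bleed-through correction arithmetic", {
  u <- function(v) matrix(v, 4, 4)
  fs <- fret_frameset(u(100), u(100), u(100))
  ft <- compute_fret_index(fs, bleedthrough_coefficients(0.55, 0.028))
  expect_equal(ft[1, 1, 1], 42.2)          # 100 - 55 - 2.8
  expect_equal(compute_fret_index(fret_frameset(u(0), u(0), u(0))),
               array(0, c(4, 4, 1)))
  expect_error(fret_frameset(u(1), matrix(1, 5, 5), u(1)), "dimensions")
})

test_that("FRET index is linear under intensity scaling", {
  set.seed(42)
  for (i in 1:5) {
    d <- array(runif(4 * 4 * 2, 0, 100), c(4, 4, 2))
    f <- array(runif(4 * 4 * 2, 0, 100), c(4, 4, 2))
    a <- array(runif(4 * 4 * 2, 0, 100), c(4, 4, 2))
    sc <- runif(1, 0.1, 10)
    f1 <- compute_fret_index(fret_frameset(d, f, a))
    f2 <- compute_fret_index(fret_frameset(sc * d, sc * f, sc * a))
    expect_equal(f2, sc * f1, tolerance = 1e-12)
  }
})

test_that("2x2 median filter uses a top-left anchor with edge replication", {
  m <- matrix(c(1, 2, 3,
                4, 5, 6,
                7, 8, 9), 3, 3, byrow = TRUE)
  fs <- fret_frameset(m * 0, m, m * 0, pixel_size_um = 0.2)
  got <- compute_fret_index(fs, bleedthrough_coefficients(0, 0), median_filter = TRUE)[, , 1]
  # oracle: median of in[r..r+1, c..c+1], replicating the last row/column
  pad <- m[c(1:3, 3), c(1:3, 3)]
  want <- matrix(0, 3, 3)
  for (r in 1:3) for (cc in 1:3)
    want[r, cc] <- median(pad[r:(r + 1), cc:(cc + 1)])
  expect_equal(got, want)
})

test_that("bleed-through slopes are recovered from single-label samples", {
  d <- array(runif(16 * 16 * 2, 10, 200), c(16, 16, 2))
  z <- array(0, dim(d))
  mask <- array(TRUE, dim(d))
  fs_d <- fret_frameset(d, 0.55 * d, z)
  expect_equal(estimate_bleedthrough(fs_d, "donor", mask), 0.55)
  a <- array(runif(16 * 16 * 2, 10, 200), c(16, 16, 2))
  fs_a <- fret_frameset(z, 0.028 * a, a)
  expect_equal(estimate_bleedthrough(fs_a, "acceptor", mask), 0.028)
  expect_error(estimate_bleedthrough(fs_d, "donor", array(FALSE, dim(d))), "empty mask")
  expect_error(estimate_bleedthrough(fret_frameset(z, z, z), "donor", mask),
               "zero-variance")

  # noisy generated donor-only sample: slope within +-0.02 of the configured value
  for (s in 1:5) {
    cfg <- scene_config(image_shape = c(64, 64), n_frames = 4, cell_radius_px = 22,
                        acceptor_expression = 0, baseline_activity = 0,
                        hotspot_activity = 0, pulse_shape = "none", seed = 500 + s)
    sc <- generate_scene(cfg)
    mk <- build_mask(sc$frames$donor, min_area_px = 40)
    expect_lt(abs(estimate_bleedthrough(sc$frames, "donor", mk) - 0.55), 0.02)
  }
})

test_that("donor-normalized FRET flags undefined pixels and matches E/(1-E)", {
  f <- matrix(10, 3, 3); d <- matrix(5, 3, 3); m <- matrix(TRUE, 3, 3)
  expect_equal(donor_normalized_fret(f, d, m, floor = 1)[1, 1, 1], 2.0)
  d[2, 2] <- 0
  out <- donor_normalized_fret(f, d, m, floor = 1)
  expect_true(is.na(out[2, 2, 1]))
  expect_false(anyNA(out[, , 1][-5]))

  cfg <- quiet_config(image_shape = c(48, 48), n_frames = 1, cell_radius_px = 16,
                      baseline_activity = 0.2, hotspot_activity = 0,
                      pulse_shape = "none", seed = 1)
  sc <- generate_scene(cfg)
  ft <- compute_fret_index(sc$frames)
  dn <- donor_normalized_fret(ft, sc$frames$donor, sc$truth$mask_truth, floor = 1)
  expect_equal(range(dn, na.rm = TRUE), rep(0.2 / 0.8, 2), tolerance = 1e-9)
})

test_that("spectral FRET efficiency is Fa/(Fa+Fd), bounded and monotone", {
  expect_equal(fret_efficiency(1, 1), 0.5)
  expect_equal(fret_efficiency(0, 2), 0)
  expect_equal(fret_efficiency(3, 1), 0.75)
  expect_error(fret_efficiency(0, 0), "positive")
  expect_error(fret_efficiency(-1, 2))
  fa <- seq(0.1, 10, length.out = 50)
  e <- fret_efficiency(fa, 2)
  expect_true(all(diff(e) > 0))
  expect_true(all(e >= 0 & e <= 1))
})

test_that("8-bit conversion scales, rounds half-up and handles degenerate input", {
  x <- array(c(0, 255, 510), c(1, 1, 3))
  y <- to_8bit(x, "global-minmax")
  expect_identical(as.integer(y), c(0L, 128L, 255L))   # 127.5 rounds up
  const <- array(7, c(2, 2))
  expect_true(all(to_8bit(const) == 0L))
  z <- array(as.numeric(0:255), c(16, 16))
  expect_identical(as.integer(to_8bit(z, "fixed-range", 0, 255)), 0:255)
  expect_error(to_8bit(array(c(1, NA), 2)), "finite")
})
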