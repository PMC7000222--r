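test_that("fractional area/perimeter changes follow the defining sums", {
  # areas 100 -> 110 -> 90: (10 + 20) / 100 / 2 = 0.15
  r1 <- matrix(FALSE, 24, 24); r1[3:12, 3:12] <- TRUE            # 100
  r2 <- matrix(FALSE, 24, 24); r2[3:12, 3:13] <- TRUE            # 110
  r3 <- matrix(FALSE, 24, 24); r3[3:11, 3:12] <- TRUE            # 90
  mo <- fractional_changes(mask_stack_from(r1, r2, r3))
  expect_equal(mo$areas_px2, c(100, 110, 90))
  expect_equal(mo$mean_fractional_area_change, 0.15)

  same <- mask_stack_from(r1, r1, r1)
  mo0 <- fractional_changes(same)
  expect_equal(mo0$mean_fractional_area_change, 0)
  expect_equal(mo0$mean_fractional_perimeter_change, 0)

  # disk growing 10 -> 11 -> 12 px: analytic pi-based value within 3%
  # (generic, non-lattice-aligned center; half-integer centers alias worst)
  ctr <- c(16.3, 16.7)
  dmo <- fractional_changes(mask_stack_from(disk_mask(33, 10, ctr),
                                            disk_mask(33, 11, ctr),
                                            disk_mask(33, 12, ctr)))
  analytic <- (pi * (11^2 - 10^2) + pi * (12^2 - 11^2)) / (pi * 10^2) / 2
  expect_lt(abs(dmo$mean_fractional_area_change - analytic) / analytic, 0.03)

  # frame reversal rescales by A_1 / A_n exactly
  rev <- fractional_changes(mask_stack_from(r3, r2, r1))
  expect_equal(rev$mean_fractional_area_change * 90,
               mo$mean_fractional_area_change * 100)
  expect_error(fractional_changes(mask_stack_from(r1)), "two frames")
})

test_that("boundary velocity is zero for static masks and scales on growth", {
  m <- disk_mask(51, 16)
  static <- mask_stack_from(m, m, m)
  vm0 <- boundary_velocity_map(static, 0.2, 0.5)
  expect_true(all(vm0$velocity_um_per_min == 0))

  grow <- mask_stack_from(disk_mask(64, 15), disk_mask(64, 16),
                          disk_mask(64, 17), disk_mask(64, 18))
  vm <- boundary_velocity_map(grow, 0.2, 0.5)
  # 1 px/frame at 0.2 um/px and 2 frames/min = 0.4 um/min, protrusion-positive
  expect_lt(abs(mean(vm$velocity_um_per_min) - 0.4) / 0.4, 0.1)
  expect_true(all(vm$velocity_um_per_min > 0))
  shrink <- mask_stack_from(disk_mask(64, 18), disk_mask(64, 15))
  expect_true(all(boundary_velocity_map(shrink, 0.2, 0.5)$velocity_um_per_min < 0))
  expect_identical(vm$motility_um_per_min, abs(vm$velocity_um_per_min))
})

test_that("motility localizes to a protruding sector", {
  H <- 64; ctr <- (H + 1) / 2
  ang <- function(m) atan2(-(row(m) - ctr), col(m) - ctr)
  mk_frame <- function(bump) {
    m <- matrix(FALSE, H, H)
    th <- ang(m)
    r <- 14 + bump * exp(-((th - pi / 4) / 0.3)^2)
    rho <- sqrt((row(m) - ctr)^2 + (col(m) - ctr)^2)
    m[rho <= r] <- TRUE
    m
  }
  ms <- mask_stack_from(mk_frame(0), mk_frame(2), mk_frame(4))
  vm <- boundary_velocity_map(ms, 0.2, 0.5)
  P <- vm$points[[1]]
  th_pts <- atan2(-(P[, 1] - ctr), P[, 2] - ctr)
  in_sector <- abs(th_pts - pi / 4) < 0.6
  expect_gt(mean(vm$motility_um_per_min[in_sector, ]),
            5 * mean(vm$motility_um_per_min[!in_sector & abs(th_pts + pi / 2) < 1, ]))
})

test_that("near-membrane signal picks up boundary-proximal intensity", {
  m <- disk_mask(51, 16)
  mk <- mask_stack_from(m, m)
  u <- array(3.5, c(51, 51, 2))
  sig <- near_membrane_signal(u, mk, depth_um = 1)
  expect_true(all(abs(sig - 3.5) < 1e-12))
  expect_error(near_membrane_signal(u, mk, depth_um = 0.1), "one pixel")

  cfg <- quiet_config(image_shape = c(64, 64), n_frames = 1, cell_radius_px = 22,
                      hotspot_angle_deg = 45, pulse_shape = "none", seed = 51)
  sc <- generate_scene(cfg)
  mk2 <- mask_stack_from_truth(sc$truth)
  sg <- near_membrane_signal(compute_fret_index(sc$frames), mk2)
  P <- boundary_velocity_map(mask_stack_from(sc$truth$mask_truth[, , 1],
                                             sc$truth$mask_truth[, , 1]),
                             0.2, 0.5)$points[[1]]
  th <- atan2(-(P[, 1] - 32.5), P[, 2] - 32.5) * 180 / pi
  hot <- abs(th - 45) < 25
  cold <- abs(th + 135) < 25 | abs(th - (-135)) < 25
  expect_gt(mean(sg[hot, 1]), mean(sg[cold, 1]) + 5)
})

test_that("binned motility-FRET correlation recovers a planted cubic exactly", {
  cubic <- function(x) 2 + 0.5 * x - 0.04 * x^2 + 0.001 * x^3
  centers <- seq(1.5, 28.5, by = 3)
  n_rep <- 20
  sig <- matrix(rep(centers, each = n_rep), ncol = 1)
  mot <- matrix(cubic(sig), ncol = 1)
  map <- structure(list(motility_um_per_min = mot,
                        velocity_um_per_min = mot,
                        pixel_size_um = 0.2, frame_interval_min = 0.5),
                   class = "boundary_motility_map")
  co <- motility_fret_correlation(map, sig)
  expect_equal(unname(co$cubic_coefficients), c(2, 0.5, -0.04, 0.001),
               tolerance = 1e-9)
  expect_equal(co$fit_r2, 1, tolerance = 1e-9)
  expect_equal(co$bins$bin_left, seq(0, 27, by = 3))

  # constant motility: degenerate fit with R^2 defined as 0
  mot0 <- matrix(1.25, nrow(sig), 1)
  map0 <- structure(list(motility_um_per_min = mot0, velocity_um_per_min = mot0,
                         pixel_size_um = 0.2, frame_interval_min = 0.5),
                    class = "boundary_motility_map")
  co0 <- motility_fret_correlation(map0, sig)
  expect_equal(unname(co0$cubic_coefficients), c(1.25, 0, 0, 0))
  expect_equal(co0$fit_r2, 0)

  few <- matrix(c(1, 2), 2, 1)
  mapf <- structure(list(motility_um_per_min = few, velocity_um_per_min = few,
                         pixel_size_um = 0.2, frame_interval_min = 0.5),
                    class = "boundary_motility_map")
  expect_error(motility_fret_correlation(mapf, few), "4 nonempty bins")
})

test_that("activity-coupled scenes show negative signal-motility correlation", {
  neg <- 0L
  for (s in 1:5) {
    cfg <- scene_config(image_shape = c(64, 64), n_frames = 12, cell_radius_px = 20,
                        boundary_motility_amp_px = 1.2, motility_coupling = -0.9,
                        seed = 800 + s)
    sc <- generate_scene(cfg)
    mk <- build_mask(sc$frames$acceptor, min_area_px = 40)
    vm <- boundary_velocity_map(mk, 0.2, 0.5)
    sig <- near_membrane_signal(compute_fret_index(sc$frames), mk)
    co <- motility_fret_correlation(vm, sig)
    neg <- neg + (co$spearman_rho < 0)
  }
  expect_gte(neg, 4L)
})
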