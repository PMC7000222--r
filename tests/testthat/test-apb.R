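test_that("donor recovery arithmetic and the delta image are exact", {
  expect_equal(donor_recovery_percent(50, 100), 50)
  expect_equal(donor_recovery_percent(80, 100), 20)
  expect_equal(donor_recovery_percent(70, 70), 0)
  expect_true(is.na(donor_recovery_percent(10, 0)))
  expect_lt(donor_recovery_percent(100, 80), 0)   # donor fell: negative, defined
  # strictly increasing in post at fixed pre
  post <- seq(10, 100, 5)
  expect_true(all(diff(donor_recovery_percent(50, post)) > 0))

  cfg <- quiet_config(image_shape = c(32, 32), n_frames = 1, cell_radius_px = 10,
                      baseline_activity = 0.25, hotspot_activity = 0,
                      pulse_shape = "none", seed = 1)
  pair <- generate_apb_pair(cfg, 0, "0X")
  expect_equal(delta_donor_image(pair), matrix(0, 32, 32))
  pair$post$donor <- pair$pre$donor + 10
  expect_equal(delta_donor_image(pair), matrix(10, 32, 32))
})

test_that("uniform full-bleach pair gives a flat 30% linescan profile", {
  cfg <- quiet_config(image_shape = c(64, 64), n_frames = 1,
                      baseline_activity = 0.3, hotspot_activity = 0,
                      pulse_shape = "none", cell_radius_px = 22, seed = 2)
  pair <- generate_apb_pair(cfg, 1, "10X")
  prof <- radial_recovery_profile(pair)
  expect_true(all(abs(prof$mean_recovery_pct - 30) < 1e-9))
  expect_equal(prof$n_lines, nrow(build_mask(pair$pre$acceptor)$boundaries[[1]]))

  # noisy uniform pairs: the 20-seed mean profile is flat to within +-1%
  # over the outer bins (inner bins pool too few distinct pixels for the
  # per-seed shot noise to average out)
  profs <- vapply(1:20, function(s) {
    cfgn <- scene_config(image_shape = c(64, 64), n_frames = 1,
                         baseline_activity = 0.3, hotspot_activity = 0,
                         pulse_shape = "none", cell_radius_px = 22,
                         boundary_motility_amp_px = 0, seed = 600 + s)
    pr <- generate_apb_pair(cfgn, 1, "10X")
    p <- radial_recovery_profile(pr, mask = mask_stack_from(pr$truth$mask))
    p$mean_recovery_pct[p$distance_bin_centers_px <= 15]
  }, numeric(15))
  expect_true(all(abs(rowMeans(profs) - 30) < 1))
})

test_that("edge-band activity confines recovery to the first bins", {
  cfg <- quiet_config(image_shape = c(64, 64), n_frames = 1,
                      baseline_activity = 0, hotspot_activity = 0.3,
                      hotspot_angular_width_deg = 360, hotspot_edge_depth_px = 2,
                      pulse_shape = "none", cell_radius_px = 22, seed = 3)
  pair <- generate_apb_pair(cfg, 1, "10X")
  mk <- mask_stack_from(pair$truth$mask)
  prof <- radial_recovery_profile(pair, mask = mk)
  expect_gt(prof$mean_recovery_pct[1], 10)
  inner <- prof$distance_bin_centers_px > 6
  expect_true(all(abs(prof$mean_recovery_pct[inner]) < 1e-9))
})

test_that("binned recovery equals the per-pixel brute-force oracle", {
  cfg <- quiet_config(image_shape = c(64, 64), n_frames = 1,
                      baseline_activity = 0.1, hotspot_activity = 0.3,
                      hotspot_edge_depth_px = 6, pulse_shape = "none",
                      cell_radius_px = 22, seed = 4)
  pair <- generate_apb_pair(cfg, 1, "10X")
  mk <- mask_stack_from(pair$truth$mask)
  prof <- radial_recovery_profile(pair, mask = mk, sampling = "nearest")
  oracle <- brute_force_recovery_bins(pair$pre$donor[, , 1], pair$post$donor[, , 1],
                                      mk$boundaries[[1]], mk$centroids[1, ])
  expect_equal(prof$mean_recovery_pct, oracle, tolerance = 1e-12)
})

test_that("geometry of the distance bins follows the radius", {
  cfg <- quiet_config(image_shape = c(32, 32), n_frames = 1, cell_radius_px = 10,
                      shape_harmonics = list(), baseline_activity = 0.2,
                      hotspot_activity = 0, pulse_shape = "none", seed = 5)
  pair <- generate_apb_pair(cfg, 1, "10X")
  prof <- radial_recovery_profile(pair, mask = mask_stack_from(pair$truth$mask),
                                  bin_width_px = 1)
  expect_true(length(prof$mean_recovery_pct) %in% 9:11)
  expect_equal(prof$distance_bin_centers_px[1], 0.5)
})

test_that("peripheral summary increases with bleach dose", {
  cfg <- quiet_config(image_shape = c(48, 48), n_frames = 1, cell_radius_px = 16,
                      baseline_activity = 0.3, hotspot_activity = 0,
                      pulse_shape = "none", seed = 6)
  mk0 <- mask_stack_from(generate_apb_pair(cfg, 1)$truth$mask)
  profs <- lapply(c("2X" = 0.2, "5X" = 0.5, "10X" = 1.0), function(b)
    radial_recovery_profile(generate_apb_pair(cfg, b, sprintf("%gX", b)), mask = mk0))
  tab <- peripheral_recovery_summary(profs, band_px = 5)
  expect_true(all(diff(tab$mean_recovery_pct) > 0))
  flat <- profs[[3]]
  expect_equal(peripheral_recovery_summary(flat, band_px = 100)$mean_recovery_pct, 30,
               tolerance = 1e-9)
  expect_error(peripheral_recovery_summary(flat, band_px = 0.1), "no bins")
})
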