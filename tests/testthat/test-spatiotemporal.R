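test_that("quadrant means are exact arithmetic means with conservation", {
  # 4x4 frame, quadrant-uniform values 1..4
  v <- matrix(0, 4, 4)
  v[1:2, 1:2] <- 1; v[1:2, 3:4] <- 2; v[3:4, 1:2] <- 3; v[3:4, 3:4] <- 4
  sq <- matrix(TRUE, 4, 4)
  mk <- mask_stack_from(sq)
  q <- quadrant_labels(mk)
  tr <- quadrant_mean_traces(v, q)
  expect_equal(unname(tr$mean_intensity[, 1]), c(1, 2, 3, 4))

  # mean of {2, 4, 6} is 4 (pixels all in the top-left quadrant)
  v2 <- matrix(0, 8, 8); v2[1, 1] <- 2; v2[1, 2] <- 4; v2[2, 1] <- 6
  m2 <- matrix(FALSE, 8, 8)
  m2[1, 1] <- m2[1, 2] <- m2[2, 1] <- TRUE
  m2[6:7, 6:7] <- TRUE                 # pushes the centroid below/right
  mk2 <- mask_stack_from(m2)
  tr2 <- quadrant_mean_traces(v2, quadrant_labels(mk2))
  expect_equal(unname(tr2$mean_intensity["Q1", 1]), 4)

  # conservation: sum_q n_q mean_q equals the total masked intensity
  cfg <- scene_config(image_shape = c(48, 48), n_frames = 3, cell_radius_px = 16, seed = 31)
  sc <- generate_scene(cfg)
  mk3 <- build_mask(sc$frames$acceptor, min_area_px = 40)
  ft <- compute_fret_index(sc$frames)
  tr3 <- quadrant_mean_traces(ft, quadrant_labels(mk3))
  for (t in 1:3) {
    lhs <- sum(tr3$mean_intensity[, t] * tr3$n_pixels[, t])
    rhs <- sum(ft[, , t][mk3$masks[, , t]])
    expect_lt(abs(lhs - rhs), 1e-9 * max(1, abs(rhs)))
  }

  # a hotspot confined to Q4 keeps the Q4 trace strictly on top
  cfg4 <- quiet_config(image_shape = c(48, 48), n_frames = 6, cell_radius_px = 16,
                       hotspot_angle_deg = -45, hotspot_angular_width_deg = 60,
                       pulse_shape = "none", seed = 32)
  sc4 <- generate_scene(cfg4)
  tr4 <- quadrant_mean_traces(compute_fret_index(sc4$frames),
                              quadrant_labels(mask_stack_from_truth(sc4$truth)))
  expect_true(all(tr4$mean_intensity["Q4", ] >
                  apply(tr4$mean_intensity[1:3, ], 2, max)))
})

test_that("compartment summary equals exhaustive search, ties resolved", {
  expect_equal(compartment_summary(traces_from_matrix(matrix(1:4, 4, 3)))$max_fret_hfq, 4)
  one <- traces_from_matrix(matrix(c(5, 1, 2, 3), 4, 1))
  s1 <- compartment_summary(one)
  expect_equal(s1$hfq_id, "Q1"); expect_equal(s1$lfq_at_same_time, 1)

  set.seed(55)
  for (i in 1:10) {
    m <- matrix(sample(1:9, 4 * 50, replace = TRUE), 4, 50)  # many ties
    tr <- traces_from_matrix(m)
    got <- compartment_summary(tr)
    want <- brute_force_compartment(m, tr$time_min)
    expect_equal(got[c("max_fret_hfq", "hfq_id", "t_at_max_min",
                       "lfq_at_same_time", "lfq_id")], want)
  }
})

test_that("stimulation deltas keep the pre-period quadrant designation", {
  pre <- traces_from_matrix(matrix(c(4, 3, 2, 1), 4, 5))
  post <- pre
  post$mean_intensity["Q1", ] <- post$mean_intensity["Q1", ] + 5
  d <- stimulation_delta(pre, post)
  expect_equal(d$hfq_id, "Q1"); expect_equal(d$lfq_id, "Q4")
  expect_equal(d$delta_hfq, 5); expect_equal(d$delta_lfq, 0)
  expect_true(d$hfq_exceeds_lfq)
  d0 <- stimulation_delta(pre, pre)
  expect_true(all(d0$delta == 0)); expect_false(d0$hfq_exceeds_lfq)

  # doubled hotspot amplitude raises the HFQ more than the LFQ
  hits <- 0L
  for (s in 1:10) {
    base <- scene_config(image_shape = c(64, 64), n_frames = 20,
                         cell_radius_px = 22, seed = 700 + s)
    stim <- base; stim$hotspot_activity <- 2 * base$hotspot_activity
    stim$seed <- 700 + s + 5000
    sc1 <- generate_scene(base); sc2 <- generate_scene(stim)
    tr1 <- quadrant_mean_traces(compute_fret_index(sc1$frames),
                                quadrant_labels(mask_stack_from_truth(sc1$truth)))
    tr2 <- quadrant_mean_traces(compute_fret_index(sc2$frames),
                                quadrant_labels(mask_stack_from_truth(sc2$truth)))
    hits <- hits + stimulation_delta(tr1, tr2)$hfq_exceeds_lfq
  }
  expect_gte(hits, 9L)
})

test_that("dominant period is exact on-grid and robust to quadratic drift", {
  t_min <- (0:99) * 0.5
  tr <- sin(2 * pi * t_min / 5)
  expect_equal(dominant_period(tr, 0.5)$dominant_period_min, 5.0)
  drifted <- tr + 0.01 * t_min^2
  expect_equal(dominant_period(drifted, 0.5)$dominant_period_min, 5.0)
  # without detrending, the drift dominates the spectrum
  expect_false(isTRUE(all.equal(
    dominant_period(drifted, 0.5, detrend = FALSE)$dominant_period_min, 5.0)))

  expect_error(dominant_period(rep(1, 20), 0.5), "no oscillatory power")
  expect_error(dominant_period(1:5, 0.5), "8 samples")
  expect_error(dominant_period(c(1:10, NA, 12:20), 0.5), "missing")

  # raised-cosine pulse train at 3.5 min over a 25-min movie: within one bin
  cfg <- quiet_config(image_shape = c(48, 48), n_frames = 50, cell_radius_px = 16,
                      seed = 41)
  sc <- generate_scene(cfg)
  tr5 <- quadrant_mean_traces(compute_fret_index(sc$frames),
                              quadrant_labels(mask_stack_from_truth(sc$truth)))
  hfq <- compartment_summary(tr5)$hfq_id
  pd <- dominant_period(tr5$mean_intensity[hfq, ], 0.5)
  fbin <- 1 / (50 * 0.5)
  expect_lte(abs(pd$dominant_frequency_cpm - 1 / 3.5), fbin + 1e-12)
  expect_equal(pd$dominant_period_min, 1 / pd$dominant_frequency_cpm)
})

test_that("sector kymograph localizes activity in distance and honors the arc", {
  # uniform disk: constant over distance and time
  m <- disk_mask(64, 22)
  mk <- mask_stack_from(m, m, pixel_size_um = 0.2)
  u <- array(7, c(64, 64, 2))
  km <- sector_kymograph(u, mk, arc_length_px = 40)
  expect_equal(km$arc_length_px, 40)
  expect_true(all(abs(km$mean_intensity - 7) < 1e-9))

  # ring of elevated intensity at a known depth from the edge
  ed <- edge_distance(m)
  ring <- (ed > 5 & ed <= 8) * 10 + 1
  img <- array(ring, c(64, 64, 1))
  km2 <- sector_kymograph(img, mask_stack_from(m), arc_length_px = 40)
  peak_bin <- which.max(km2$mean_intensity[, 1])
  expect_true(km2$distance_bins_px[peak_bin] >= 4.5 &&
              km2$distance_bins_px[peak_bin] <= 8.5)

  # auto-max anchors the arc on the hottest membrane region
  cfg <- quiet_config(image_shape = c(64, 64), n_frames = 2, cell_radius_px = 22,
                      hotspot_angle_deg = 45, pulse_shape = "none", seed = 42)
  sc <- generate_scene(cfg)
  mk3 <- mask_stack_from_truth(sc$truth)
  km3 <- sector_kymograph(compute_fret_index(sc$frames), mk3)
  ang <- km3$sector_angle_range_deg
  expect_true(any(abs(c(ang, mean(ang)) - 45) < 60))
  expect_error(sector_kymograph(u, mk, arc_length_px = 10000), "longer than")
})
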