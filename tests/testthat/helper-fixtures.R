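# Fixtures and independent oracles used across the suite.

# Filled disk mask of radius r centered in an H x H frame.
disk_mask <- function(H, r, center = c((H + 1) / 2, (H + 1) / 2)) {
  m <- matrix(FALSE, H, H)
  rr <- row(m) - center[1]; cc <- col(m) - center[2]
  m[rr^2 + cc^2 <= r^2] <- TRUE
  m
}

# Assemble a cell_mask_stack directly from binary masks (bypasses build_mask,
# for tests that need exact hand-constructed geometry).
mask_stack_from <- function(..., pixel_size_um = 0.2) {
  ms <- list(...)
  if (length(ms) == 1L && is.array(ms[[1]]) && length(dim(ms[[1]])) == 3L)
    ms <- lapply(seq_len(dim(ms[[1]])[3]), function(t) ms[[1]][, , t])
  arr <- array(FALSE, c(dim(ms[[1]]), length(ms)))
  cents <- matrix(NA_real_, length(ms), 2)
  bnds <- vector("list", length(ms))
  for (t in seq_along(ms)) {
    arr[, , t] <- ms[[t]]
    cents[t, ] <- colMeans(which(ms[[t]], arr.ind = TRUE))
    bnds[[t]] <- trace_boundary(ms[[t]])
  }
  structure(list(masks = arr, centroids = cents, boundaries = bnds,
                 areas_px2 = vapply(ms, sum, numeric(1)),
                 pixel_size_um = pixel_size_um),
            class = "cell_mask_stack")
}

# Mask stack taken from generator ground truth (centroids recomputed).
mask_stack_from_truth <- function(truth, pixel_size_um = 0.2) {
  mask_stack_from(truth$mask_truth, pixel_size_um = pixel_size_um)
}

# Quadrant-trace object from a plain matrix (rows Q1..Q4).
traces_from_matrix <- function(m, frame_interval_min = 0.5) {
  rownames(m) <- paste0("Q", 1:4)
  structure(list(time_min = (seq_len(ncol(m)) - 1) * frame_interval_min,
                 mean_intensity = m,
                 n_pixels = matrix(1L, 4, ncol(m))),
            class = "quadrant_traces")
}

# Brute-force Euclidean distance transform: per foreground pixel, scan every
# background pixel.
brute_force_edt <- function(mask) {
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2
    out[fg[i, 1], fg[i, 2]] <- sqrt(min(d2))
  }
  out
}

# Exhaustive-search oracle for the HFQ/LFQ summary: scan all (quadrant, time)
# cells, earliest time then lowest quadrant on ties.
brute_force_compartment <- function(m, time_min) {
  best <- -Inf; bq <- NA; bt <- NA
  for (t in seq_len(ncol(m))) for (q in 1:4) {
    v <- m[q, t]
    if (!is.na(v) && v > best) { best <- v; bq <- q; bt <- t }
  }
  col <- m[, bt]
  lq <- which.min(col)
  list(max_fret_hfq = best, hfq_id = paste0("Q", bq), t_at_max_min = time_min[bt],
       lfq_at_same_time = unname(col[lq]), lfq_id = paste0("Q", lq))
}

# Independent linescan oracle with nearest-pixel sampling: donor recovery per
# distance bin recomputed with a plain per-line loop.
brute_force_recovery_bins <- function(pre, post, boundary, centroid, bin_width = 1) {
  sums_pre <- numeric(0); sums_post <- numeric(0); cnt <- numeric(0)
  for (i in seq_len(nrow(boundary))) {
    p <- boundary[i, ]
    v <- centroid - p
    L <- sqrt(sum(v^2))
    for (s in 0:floor(L)) {
      r <- round(p[1] + v[1] * s / max(L, 1e-12))
      c <- round(p[2] + v[2] * s / max(L, 1e-12))
      b <- floor(s / bin_width) + 1L
      if (b > length(cnt)) {
        sums_pre[b] <- 0; sums_post[b] <- 0; cnt[b] <- 0
      }
      sums_pre[b] <- sums_pre[b] + pre[r, c]
      sums_post[b] <- sums_post[b] + post[r, c]
      cnt[b] <- cnt[b] + 1
    }
  }
  keep <- cnt > 0
  (1 - (sums_pre[keep] / cnt[keep]) / (sums_post[keep] / cnt[keep])) * 100
}

# Quiet scene: no noise, no motion, fixed footprint.
quiet_config <- function(...) {
  scene_config(gauss_noise_sd = 0, poisson_like = FALSE,
               boundary_motility_amp_px = 0, ...)
}
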