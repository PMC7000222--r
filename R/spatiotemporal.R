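#' Per-quadrant mean FRET_T traces
#'
#' Mean intensity = sum of pixel values in the quadrant divided by the number
#' of pixels, per quadrant per frame, over mask-interior pixels only.  An
#' empty quadrant yields NA for that frame.
#'
#' @param fret_index H x W x T array (FRET_T or any aligned intensity stack).
#' @param quadrants integer array from [quadrant_labels()].
#' @param frame_interval_min minutes per frame for the time axis.
#' @return `quadrant_traces`: list with `time_min`, `mean_intensity`
#'   (4 x T, rows Q1..Q4) and `n_pixels` (4 x T).
#' @export
quadrant_mean_traces <- function(fret_index, quadrants, frame_interval_min = 0.5) {
  fret_index <- as_stack(fret_index); quadrants <- as_stack(quadrants)
  if (!identical(dim(fret_index), dim(quadrants))) stop("shape mismatch")
  T_ <- dim(fret_index)[3]
  mi <- matrix(NA_real_, 4, T_, dimnames = list(paste0("Q", 1:4), NULL))
  np <- matrix(0L, 4, T_, dimnames = list(paste0("Q", 1:4), NULL))
  for (t in seq_len(T_)) {
    q <- quadrants[, , t]; v <- fret_index[, , t]
    for (k in 1:4) {
      sel <- q == k
      n <- sum(sel)
      np[k, t] <- n
      if (n > 0L) mi[k, t] <- sum(v[sel]) / n
    }
  }
  structure(list(time_min = (seq_len(T_) - 1) * frame_interval_min,
                 mean_intensity = mi, n_pixels = np),
            class = "quadrant_traces")
}

#' High- and low-FRET quadrant summary
#'
#' The high-FRET quadrant (HFQ) and its Max-FRET_T value are located at the
#' global maximum of the quadrant-mean table over quadrants and time; the
#' low-FRET quadrant (LFQ) value is the minimum quadrant mean read at that
#' same time point.  Ties are broken by earliest time, then lowest quadrant
#' index.
#'
#' @param traces a `quadrant_traces`.
#' @return list with `max_fret_hfq`, `hfq_id`, `t_at_max_min`, `frame_at_max`,
#'   `lfq_at_same_time`, `lfq_id`.
#' @export
compartment_summary <- function(traces) {
  m <- traces$mean_intensity
  if (all(is.na(m))) stop("all quadrant means are undefined")
  best <- max(m, na.rm = TRUE)
  hits <- which(m == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]  # time, then quadrant
  q <- hits[1, 1]; t <- hits[1, 2]
  col <- m[, t]
  lfq <- which.min(col)   # first (lowest index) minimum
  list(max_fret_hfq = best, hfq_id = paste0("Q", q),
       t_at_max_min = traces$time_min[t], frame_at_max = unname(t),
       lfq_at_same_time = unname(col[lfq]), lfq_id = paste0("Q", lfq))
}

#' Per-quadrant change in Max-FRET_T upon stimulation
#'
#' Quadrant designations (HFQ/LFQ) are fixed from the pre-stimulation period;
#' the delta per quadrant is the difference of its maximal mean FRET_T after
#' versus before stimulation.
#'
#' @param traces_pre,traces_post `quadrant_traces` before/after stimulation.
#' @return list with `delta` (named per-quadrant vector), `hfq_id`, `lfq_id`,
#'   `delta_hfq`, `delta_lfq`, `hfq_exceeds_lfq`.
#' @export
stimulation_delta <- function(traces_pre, traces_post) {
  s <- compartment_summary(traces_pre)
  mx <- function(tr) apply(tr$mean_intensity, 1, function(z)
    if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE))
  delta <- mx(traces_post) - mx(traces_pre)
  dh <- unname(delta[s$hfq_id]); dl <- unname(delta[s$lfq_id])
  list(delta = delta, hfq_id = s$hfq_id, lfq_id = s$lfq_id,
       delta_hfq = dh, delta_lfq = dl,
       hfq_exceeds_lfq = isTRUE(dh > dl))
}

#' Dominant pulse period of an activity trace
#'
#' A least-squares quadratic trend is removed, then a one-sided periodogram
#' (rectangular window, no padding) is computed; the dominant frequency is the
#' argmax of power excluding the zero bin (ties go to the lowest frequency),
#' and the period is its reciprocal in minutes.
#'
#' @param trace numeric vector, uniformly sampled, at least 8 samples, no NA.
#' @param frame_interval_min sampling interval in minutes.
#' @param detrend remove the quadratic trend first (default TRUE).
#' @return `psd_result`: list with `frequency_grid_cpm`, `power`,
#'   `dominant_frequency_cpm`, `dominant_period_min`.
#' @export
dominant_period <- function(trace, frame_interval_min = 0.5, detrend = TRUE) {
  if (anyNA(trace)) stop("trace contains missing samples; resampling is not supported")
  n <- length(trace)
  if (n < 8L) stop("at least 8 samples are required")
  stopifnot(frame_interval_min > 0)
  x <- as.numeric(trace)
  if (detrend) {
    tt <- seq_len(n) - 1
    x <- resid(lm(x ~ tt + I(tt^2)))
  } else {
    x <- x - mean(x)
  }
  if (sd(x) < .Machine$double.eps^0.5 * (1 + max(abs(trace))))
    stop("no oscillatory power: trace is constant after detrending")
  X <- fft(x)
  nk <- floor(n / 2)
  power <- (Mod(X[2:(nk + 1L)])^2) * frame_interval_min / n
  freq <- (1:nk) / (n * frame_interval_min)
  k <- which.max(power)    # first maximum = lowest frequency on ties
  structure(list(frequency_grid_cpm = freq, power = power,
                 dominant_frequency_cpm = freq[k],
                 dominant_period_min = 1 / freq[k]),
            class = "psd_result")
}

#' Mean dominant period across quadrant traces of one cell
#'
#' Applies [dominant_period()] to each quadrant trace and averages the
#' periods; quadrants whose trace is constant after detrending are skipped.
#'
#' @param traces a `quadrant_traces`.
#' @param detrend passed to [dominant_period()].
#' @return list with `period_per_quadrant_min` and `mean_period_min`.
#' @export
dominant_period_cell <- function(traces, detrend = TRUE) {
  dt <- diff(traces$time_min[1:2])
  per <- apply(traces$mean_intensity, 1, function(z) {
    if (anyNA(z)) return(NA_real_)
    res <- tryCatch(dominant_period(z, dt, detrend), error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$dominant_period_min
  })
  list(period_per_quadrant_min = per,
       mean_period_min = mean(per, na.rm = TRUE))
}

#' Sector kymograph: activity versus time and distance from the membrane
#'
#' An arc of `arc_length_px` boundary pixels is anchored on the membrane —
#' either at a given boundary index or at the boundary position with maximal
#' nearby FRET_T (`"auto-max"`: per-boundary-pixel mean over the first
#' `probe_depth_px` ray samples, circularly smoothed over an arc-length
#' window).  The sector is the union of the straight segments from the arc
#' pixels to the centroid; intensities along those rays are pooled per frame
#' into distance-from-edge bins.  Geometry is fixed on `reference_frame`.
#'
#' @param fret_index H x W x T array.
#' @param mask_stack `cell_mask_stack`.
#' @param arc_center `"auto-max"` or an integer boundary index.
#' @param arc_length_px arc length on the membrane, in boundary pixels.
#' @param radial_bin_px bin width for the distance-from-edge axis.
#' @param reference_frame frame whose boundary/centroid define the sector.
#' @param probe_depth_px ray depth used by the auto-max search.
#' @return `sector_kymograph`: list with `distance_bins_px` (centers),
#'   `time_min`, `mean_intensity` (bins x T), `arc_length_px`, `arc_indices`,
#'   `sector_angle_range_deg`.
#' @export
sector_kymograph <- function(fret_index, mask_stack, arc_center = "auto-max",
                             arc_length_px = 40L, radial_bin_px = 1,
                             reference_frame = 1L, probe_depth_px = 5L) {
  fret_index <- as_stack(fret_index)
  T_ <- dim(fret_index)[3]
  boundary <- mask_stack$boundaries[[reference_frame]]
  centroid <- mask_stack$centroids[reference_frame, ]
  nb <- nrow(boundary)
  if (arc_length_px > nb) stop("arc longer than the boundary")
  ref <- fret_index[, , reference_frame]
  if (identical(arc_center, "auto-max")) {
    near <- vapply(seq_len(nb), function(i) {
      p <- boundary[i, ]; v <- centroid - p; L <- sqrt(sum(v^2))
      st <- seq(0, min(probe_depth_px, floor(L)))
      mean(bilinear_sample(ref, p[1] + v[1] * st / max(L, 1e-12),
                           p[2] + v[2] * st / max(L, 1e-12)))
    }, numeric(1))
    w <- max(3L, arc_length_px)
    sm_near <- circular_smooth(near, w)
    arc_center <- which.max(sm_near)
  }
  half <- (arc_length_px - 1L) %/% 2L
  arc_idx <- ((arc_center - half - 1L + seq_len(arc_length_px) - 1L) %% nb) + 1L
  # pool ray samples of the arc into distance bins, per frame
  rs <- cs <- ds <- vector("list", length(arc_idx))
  for (j in seq_along(arc_idx)) {
    p <- boundary[arc_idx[j], ]
    v <- centroid - p; L <- sqrt(sum(v^2))
    st <- seq(0, floor(L))
    rs[[j]] <- p[1] + v[1] * st / max(L, 1e-12)
    cs[[j]] <- p[2] + v[2] * st / max(L, 1e-12)
    ds[[j]] <- st
  }
  r <- unlist(rs); c <- unlist(cs); d <- unlist(ds)
  bin <- floor(d / radial_bin_px) + 1L
  nbin <- max(bin)
  km <- matrix(NA_real_, nbin, T_)
  for (t in seq_len(T_)) {
    vals <- bilinear_sample(fret_index[, , t], r, c)
    km[, t] <- vapply(seq_len(nbin), function(b)
      if (any(bin == b)) mean(vals[bin == b]) else NA_real_, numeric(1))
  }
  ang <- atan2(-(boundary[arc_idx, 1] - centroid[1]),
               boundary[arc_idx, 2] - centroid[2]) * 180 / pi
  structure(list(distance_bins_px = (seq_len(nbin) - 0.5) * radial_bin_px,
                 time_min = (seq_len(T_) - 1) * attr_or(mask_stack, "frame_interval_min", 0.5),
                 mean_intensity = km,
                 arc_length_px = arc_length_px,
                 arc_indices = arc_idx,
                 arc_center = arc_center,
                 sector_angle_range_deg = range(ang)),
            class = "sector_kymograph")
}

attr_or <- function(x, name, default) {
  v <- x[[name]]
  if (is.null(v)) default else v
}

# Circular moving average with an odd-sized window.
circular_smooth <- function(x, w) {
  n <- length(x)
  w <- min(w, n)
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  idx <- outer(seq_len(n), -half:half, function(i, k) ((i + k - 1L) %% n) + 1L)
  rowMeans(matrix(x[idx], n))
}
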