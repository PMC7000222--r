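#' Mean fractional area and perimeter change of a cell
#'
#' Frame-to-frame changes of footprint area and boundary length, normalized to
#' the first frame and averaged:
#' mean fractional area change = sum_i |A_{i+1} - A_i| / A_1 / (n - 1), and
#' the analogous quantity for the perimeter.  The perimeter is the boundary
#' chain length with diagonal steps weighted sqrt(2) (uncorrected; the
#' normalization cancels any constant correction factor).
#'
#' @param mask_stack `cell_mask_stack` with at least two frames.
#' @return `morpho_result`: list with `areas_px2`, `perimeters_px`,
#'   `mean_fractional_area_change`, `mean_fractional_perimeter_change`.
#' @export
fractional_changes <- function(mask_stack) {
  stopifnot(inherits(mask_stack, "cell_mask_stack"))
  n <- dim(mask_stack$masks)[3]
  if (n < 2L) stop("at least two frames are required")
  areas <- mask_stack$areas_px2
  perims <- vapply(mask_stack$boundaries, chain_length, numeric(1))
  structure(list(areas_px2 = areas, perimeters_px = perims,
                 mean_fractional_area_change = sum(abs(diff(areas))) / areas[1] / (n - 1),
                 mean_fractional_perimeter_change = sum(abs(diff(perims))) / perims[1] / (n - 1)),
            class = "morpho_result")
}

# Resample a closed pixel boundary to n arc-length-uniform points, optionally
# smoothing the result with a circular moving average (subpixel boundary
# estimate; removes the +-0.5 px staircase of the pixel chain).
resample_boundary <- function(boundary, n, smooth_window = 0L) {
  b <- boundary
  if (nrow(b) < 2L) return(matrix(rep(as.numeric(b), each = n), n, 2))
  closed <- rbind(b, b[1, ])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] - closed[-nrow(closed), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  frac <- (s - cum[idx]) / pmax(seg[idx], 1e-12)
  pts <- closed[idx, , drop = FALSE] +
    frac * (closed[idx + 1L, , drop = FALSE] - closed[idx, , drop = FALSE])
  if (smooth_window > 1L) {
    pts[, 1] <- circular_smooth(pts[, 1], smooth_window)
    pts[, 2] <- circular_smooth(pts[, 2], smooth_window)
  }
  pts
}

# Minimum distance from points P (m x 2) to a closed polyline B (k x 2).
dist_to_polyline <- function(P, B) {
  A1 <- B
  A2 <- rbind(B[-1, , drop = FALSE], B[1, , drop = FALSE])
  ex <- A2[, 1] - A1[, 1]; ey <- A2[, 2] - A1[, 2]
  ee <- pmax(ex^2 + ey^2, 1e-12)
  out <- numeric(nrow(P))
  for (i in seq_len(nrow(P))) {
    wx <- P[i, 1] - A1[, 1]; wy <- P[i, 2] - A1[, 2]
    tt <- pmin(pmax((wx * ex + wy * ey) / ee, 0), 1)
    dx <- wx - tt * ex; dy <- wy - tt * ey
    out[i] <- sqrt(min(dx^2 + dy^2))
  }
  out
}

#' Signed boundary-velocity and motility map
#'
#' The boundary of each frame is resampled to `n_boundary_samples`
#' arc-length-uniform points (circularly smoothed to sub-pixel accuracy).  The
#' signed velocity at a point is its Euclidean distance to the next frame's
#' (smoothed) boundary polyline, positive when the point lies inside the next
#' frame's mask (the membrane moved outward: protrusion) and negative outside
#' (retraction), divided by the frame interval and scaled to um/min.
#' Motility is the modulus of the velocity.
#'
#' This is a deliberately simple, self-contained boundary-velocity stage; no
#' numeric equivalence to active-contour trackers is claimed.
#'
#' @param mask_stack `cell_mask_stack` with at least two frames.
#' @param pixel_size_um,frame_interval_min acquisition scale.
#' @param n_boundary_samples boundary sampling resolution.
#' @param smooth_window circular smoothing window (boundary points).
#' @return `boundary_motility_map`: list with `velocity_um_per_min` and
#'   `motility_um_per_min` (n_boundary_samples x (T-1)), `points` (list of
#'   per-frame resampled boundary points), `pixel_size_um`,
#'   `frame_interval_min`.
#' @export
boundary_velocity_map <- function(mask_stack, pixel_size_um = NULL,
                                  frame_interval_min = 0.5,
                                  n_boundary_samples = 100L,
                                  smooth_window = 7L) {
  stopifnot(inherits(mask_stack, "cell_mask_stack"))
  if (is.null(pixel_size_um)) pixel_size_um <- mask_stack$pixel_size_um
  T_ <- dim(mask_stack$masks)[3]
  if (T_ < 2L) stop("at least two frames are required")
  # smooth once on a dense polyline and subsample the tracked points from it,
  # so identical masks yield identical curves (and exactly zero velocity)
  dense_factor <- 4L
  dense_n <- dense_factor * n_boundary_samples
  dense <- lapply(seq_len(T_), function(t)
    resample_boundary(mask_stack$boundaries[[t]], dense_n,
                      dense_factor * smooth_window))
  pts <- lapply(dense, function(d)
    d[seq(1L, dense_n, by = dense_factor), , drop = FALSE])
  vel <- matrix(0, n_boundary_samples, T_ - 1L)
  for (t in seq_len(T_ - 1L)) {
    P <- pts[[t]]
    d <- dist_to_polyline(P, dense[[t + 1L]])
    nxt <- mask_stack$masks[, , t + 1L]
    rr <- pmin(pmax(round(P[, 1]), 1L), nrow(nxt))
    cc <- pmin(pmax(round(P[, 2]), 1L), ncol(nxt))
    inside <- nxt[cbind(rr, cc)]
    vel[, t] <- ifelse(inside, d, -d) * pixel_size_um / frame_interval_min
  }
  structure(list(velocity_um_per_min = vel,
                 motility_um_per_min = abs(vel),
                 points = pts,
                 pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min,
                 n_boundary_samples = n_boundary_samples),
            class = "boundary_motility_map")
}

#' Near-membrane signal along the boundary
#'
#' For each resampled boundary point, the mean FRET_T over samples taken
#' inward along the ray to the centroid down to `depth_um` (unit pixel steps,
#' bilinear interpolation) — the activity "approximately 1 um from the
#' membrane".
#'
#' @param fret_index H x W x T array.
#' @param mask_stack `cell_mask_stack`.
#' @param depth_um inward depth; must be at least one pixel.
#' @param n_boundary_samples,smooth_window boundary sampling as in
#'   [boundary_velocity_map()] (use identical values to pair the grids).
#' @return n_boundary_samples x T matrix of mean near-membrane intensity.
#' @export
near_membrane_signal <- function(fret_index, mask_stack, depth_um = 1.0,
                                 n_boundary_samples = 100L, smooth_window = 7L) {
  fret_index <- as_stack(fret_index)
  px <- mask_stack$pixel_size_um
  depth_px <- depth_um / px
  if (depth_px < 1) stop("depth must be at least one pixel")
  T_ <- dim(fret_index)[3]
  sig <- matrix(NA_real_, n_boundary_samples, T_)
  steps <- seq(0, round(depth_px))
  for (t in seq_len(T_)) {
    P <- resample_boundary(mask_stack$boundaries[[t]], n_boundary_samples, smooth_window)
    ce <- mask_stack$centroids[t, ]
    fr <- fret_index[, , t]
    for (i in seq_len(n_boundary_samples)) {
      v <- ce - P[i, ]
      L <- sqrt(sum(v^2))
      st <- steps[steps <= L]
      if (!length(st)) st <- 0
      sig[i, t] <- mean(bilinear_sample(fr, P[i, 1] + v[1] * st / max(L, 1e-12),
                                        P[i, 2] + v[2] * st / max(L, 1e-12)))
    }
  }
  sig
}

#' Binned FRET-versus-motility correlation with cubic fit
#'
#' Pairs every near-membrane signal sample with the motility at the same
#' boundary position and frame, bins the signal into left-closed width-3 bins
#' aligned to multiples of 3 ([3k, 3k+3)), averages motility per bin, and fits
#' the cubic f = y0 + a x + b x^2 + c x^3 to the bin means against bin
#' centers by least squares.  R^2 of a zero-variance response is defined as 0.
#'
#' @param map a `boundary_motility_map`.
#' @param signal matrix from [near_membrane_signal()] on the same grid (its
#'   first T-1 columns are paired with the velocity columns).
#' @param bin_width signal bin width (3 intensity units by default).
#' @return `motility_correlation`: list with `bins` (data.frame of bin_left,
#'   bin_center, mean_motility, n), `cubic_coefficients` (y0, a, b, c),
#'   `fit_r2`, `spearman_rho`.
#' @export
motility_fret_correlation <- function(map, signal, bin_width = 3) {
  stopifnot(inherits(map, "boundary_motility_map"))
  mot <- map$motility_um_per_min
  if (nrow(signal) != nrow(mot) || ncol(signal) < ncol(mot))
    stop("signal and motility grids are not aligned")
  sig <- signal[, seq_len(ncol(mot)), drop = FALSE]
  ok <- is.finite(sig) & is.finite(mot)
  s <- sig[ok]; m <- mot[ok]
  left <- floor(s / bin_width) * bin_width
  agg <- tapply(m, left, mean)
  cnt <- tapply(m, left, length)
  lefts <- as.numeric(names(agg))
  centers <- lefts + bin_width / 2
  bins <- data.frame(bin_left = lefts, bin_center = centers,
                     mean_motility = as.numeric(agg), n = as.integer(cnt))
  if (nrow(bins) < 4L) stop("need at least 4 nonempty bins for the cubic fit")
  y <- bins$mean_motility; x <- bins$bin_center
  if (stats::var(y) == 0) {
    coefs <- c(y0 = y[1], a = 0, b = 0, c = 0)
    r2 <- 0
  } else {
    fit <- lm(y ~ x + I(x^2) + I(x^3))
    coefs <- setNames(coef(fit), c("y0", "a", "b", "c"))
    ss_res <- sum(resid(fit)^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- 1 - ss_res / ss_tot
  }
  structure(list(bins = bins, cubic_coefficients = coefs, fit_r2 = unname(r2),
                 spearman_rho = suppressWarnings(cor(x, y, method = "spearman"))),
            class = "motility_correlation")
}
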