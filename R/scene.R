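#' Configuration of a synthetic biosensor scene
#'
#' Describes a single adherent cell imaged in three channels (donor Dex-Dem,
#' raw FRET Dex-Aem, acceptor Aex-Aem).  Geometry is a star-convex radial
#' footprint r(theta, t) deformed by fixed shape harmonics plus per-frame
#' motility jitter; activity (the true FRET fraction E in [0,1)) is a baseline
#' plus a membrane-proximal angular hotspot whose amplitude pulses in time.
#'
#' Defaults follow the acquisition and biology the package targets: 0.2
#' um/pixel, 2 frames/min, pulse period 3.5 min, bleed-through slopes
#' alpha_D = 0.55 and alpha_A = 0.028.  Expression levels and noise magnitudes
#' are free parameters (no detector gain is published); defaults of ~100
#' photon-scale units with unit-gain shot noise plus read noise of 2 are
#' typical of photon-counting confocal detectors.
#'
#' @param image_shape c(rows, cols) in pixels.
#' @param n_frames number of frames.
#' @param pixel_size_um microns per pixel.
#' @param frame_interval_min minutes per frame (0.5 = 2 frames/min).
#' @param cell_radius_px mean footprint radius.
#' @param shape_harmonics list of c(order, amplitude, phase) radial
#'   perturbations, amplitude relative to the mean radius.
#' @param boundary_motility_amp_px RMS amplitude (pixels) of the per-frame
#'   radial jitter that emulates protrusion/retraction.
#' @param motility_coupling kappa in [-1, 0]: scales the jitter by
#'   (1 + kappa * hotspot profile), so kappa < 0 suppresses motility where
#'   activity is high.
#' @param hotspot_angle_deg,hotspot_angular_width_deg angular position/extent
#'   of the hotspot (0 deg = +x axis, counter-clockwise with y up, i.e. 45 deg
#'   points to the top-right image quadrant).
#' @param hotspot_edge_depth_px hotspot extends this many pixels inward from
#'   the boundary (hard cutoff in radial depth).
#' @param baseline_activity,hotspot_activity FRET-fraction levels in [0,1).
#' @param pulse_period_min,pulse_amplitude,pulse_shape,pulse_duty temporal
#'   modulation of the hotspot: raised-cosine pulse train (default), pure
#'   sinusoid, or none.
#' @param drift_quadratic_coeffs c(c0, c1, c2): slow trend c0 + c1 t + c2 t^2
#'   (t in minutes) added to activity inside the cell.
#' @param donor_expression,acceptor_expression mean photon-scale intensities
#'   inside the cell; set one of them to 0 (with zero activity) to emulate a
#'   single-label calibration sample.
#' @param alpha_D,alpha_A bleed-through slopes applied at render time.
#' @param gauss_noise_sd additive read-noise SD; `poisson_like = TRUE` adds
#'   shot noise with variance `poisson_gain * signal`.
#' @param poisson_like,poisson_gain noise model switches.
#' @param seed RNG seed for deterministic rendering (NULL = use current RNG).
#' @return `scene_config` list.
#' @export
scene_config <- function(image_shape = c(96L, 96L), n_frames = 50L,
                         pixel_size_um = 0.2, frame_interval_min = 0.5,
                         cell_radius_px = 30,
                         shape_harmonics = list(c(3, 0.08, 0.7), c(5, 0.04, 2.1)),
                         boundary_motility_amp_px = 0.6,
                         motility_coupling = 0,
                         hotspot_angle_deg = 45,
                         hotspot_angular_width_deg = 80,
                         hotspot_edge_depth_px = 8,
                         baseline_activity = 0.05,
                         hotspot_activity = 0.25,
                         pulse_period_min = 3.5,
                         pulse_amplitude = 0.12,
                         pulse_shape = c("raised_cosine", "sine", "none"),
                         pulse_duty = 0.5,
                         drift_quadratic_coeffs = c(0, 0, 0),
                         donor_expression = 100,
                         acceptor_expression = 100,
                         alpha_D = 0.55, alpha_A = 0.028,
                         gauss_noise_sd = 2,
                         poisson_like = TRUE, poisson_gain = 1,
                         seed = NULL) {
  cfg <- list(image_shape = as.integer(image_shape), n_frames = as.integer(n_frames),
              pixel_size_um = pixel_size_um, frame_interval_min = frame_interval_min,
              cell_radius_px = cell_radius_px, shape_harmonics = shape_harmonics,
              boundary_motility_amp_px = boundary_motility_amp_px,
              motility_coupling = motility_coupling,
              hotspot_angle_deg = hotspot_angle_deg,
              hotspot_angular_width_deg = hotspot_angular_width_deg,
              hotspot_edge_depth_px = hotspot_edge_depth_px,
              baseline_activity = baseline_activity,
              hotspot_activity = hotspot_activity,
              pulse_period_min = pulse_period_min,
              pulse_amplitude = pulse_amplitude,
              pulse_shape = match.arg(pulse_shape), pulse_duty = pulse_duty,
              drift_quadratic_coeffs = drift_quadratic_coeffs,
              donor_expression = donor_expression,
              acceptor_expression = acceptor_expression,
              alpha_D = alpha_D, alpha_A = alpha_A,
              gauss_noise_sd = gauss_noise_sd,
              poisson_like = poisson_like, poisson_gain = poisson_gain,
              seed = seed)
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot(length(cfg$image_shape) == 2, all(cfg$image_shape >= 8),
            cfg$n_frames >= 1, cfg$pixel_size_um > 0, cfg$frame_interval_min > 0,
            cfg$cell_radius_px > 2)
  if (cfg$baseline_activity < 0 || cfg$hotspot_activity < 0)
    stop("activity levels must be non-negative")
  if (cfg$alpha_D < 0 || cfg$alpha_D >= 1 || cfg$alpha_A < 0 || cfg$alpha_A >= 1)
    stop("bleed-through slopes must lie in [0, 1)")
  if (cfg$donor_expression < 0 || cfg$acceptor_expression < 0)
    stop("expression levels must be non-negative")
  if (cfg$pulse_shape != "none" && cfg$pulse_period_min <= 2 * cfg$frame_interval_min)
    stop("pulse period must exceed twice the frame interval to be resolvable")
  amp_sum <- if (length(cfg$shape_harmonics))
    sum(vapply(cfg$shape_harmonics, function(h) abs(h[2]), numeric(1))) else 0
  r_max <- cfg$cell_radius_px * (1 + amp_sum) + 3 * cfg$boundary_motility_amp_px
  if (r_max >= min(cfg$image_shape) / 2 - 1)
    stop(sprintf("cell radius too large for the image (max footprint %.1f px, limit %.1f)",
                 r_max, min(cfg$image_shape) / 2 - 1))
  t_min <- (seq_len(cfg$n_frames) - 1) * cfg$frame_interval_min
  dr <- cfg$drift_quadratic_coeffs
  drift <- dr[1] + dr[2] * t_min + dr[3] * t_min^2
  pulse_max <- if (cfg$pulse_shape == "none") 0 else cfg$pulse_amplitude
  e_max <- cfg$baseline_activity + cfg$hotspot_activity + pulse_max + max(drift, 0)
  e_min <- cfg$baseline_activity + min(drift, 0)
  if (e_max >= 1)
    stop(sprintf("configured activity peaks at %.3f; the FRET fraction must stay below 1", e_max))
  if (e_min < 0)
    stop("drift drives activity negative")
  invisible(cfg)
}

# Temporal pulse waveform in [0, 1].
pulse_waveform <- function(t_min, period_min, shape, duty = 0.5) {
  switch(shape,
    none = rep(0, length(t_min)),
    sine = 0.5 * (1 + sin(2 * pi * t_min / period_min)),
    raised_cosine = {
      phase <- (t_min %% period_min) / period_min
      ifelse(phase < duty, 0.5 * (1 - cos(2 * pi * phase / duty)), 0)
    })
}

# Smooth angular hotspot profile in [0, 1], hard-limited to the stated width.
hotspot_angular_profile <- function(theta, center_deg, width_deg) {
  d <- theta - center_deg * pi / 180
  d <- atan2(sin(d), cos(d))  # wrap to (-pi, pi]
  half <- (width_deg / 2) * pi / 180
  ifelse(abs(d) <= half, 0.5 * (1 + cos(pi * d / half)), 0)
}

# Radius of the footprint at angles theta for one frame. jitter_h: list of
# per-frame jitter harmonics (amplitude, phase) or NULL.
scene_radius <- function(theta, cfg, jitter_h = NULL) {
  r <- rep(1, length(theta))
  for (h in cfg$shape_harmonics) r <- r + h[2] * sin(h[1] * theta + h[3])
  r <- r * cfg$cell_radius_px
  if (!is.null(jitter_h)) {
    j <- rep(0, length(theta))
    for (h in jitter_h) j <- j + h$amp * sin(h$order * theta + h$phase)
    couple <- 1 + cfg$motility_coupling *
      hotspot_angular_profile(theta, cfg$hotspot_angle_deg, cfg$hotspot_angular_width_deg)
    r <- r + j * couple
  }
  r
}

# Add detector noise to a non-negative intensity field.
add_noise <- function(x, cfg) {
  v <- cfg$gauss_noise_sd^2 + if (cfg$poisson_like) cfg$poisson_gain * pmax(x, 0) else 0
  if (all(v == 0)) return(x)
  pmax(x + rnorm(length(x), sd = sqrt(v)), 0)
}

#' Generate a seeded synthetic three-channel time-lapse scene
#'
#' Rendering model (noise-free truth): true donor = D (1 - E), true sensitized
#' emission = D E, true acceptor = A, where D/A are the expression levels and
#' E(x, t) the activity field; the measured Dex-Aem channel is
#' sensitized + alpha_D donor + alpha_A acceptor.  Noise is applied last, so a
#' zero-noise scene round-trips exactly through the FRET-index computation.
#'
#' @param config a [scene_config()].
#' @return list with `frames` (a [fret_frameset()]) and `truth`
#'   (`scene_truth`: `activity_field`, `mask_truth`, `sensitized_truth`,
#'   `donor_truth`, `acceptor_truth`, `boundary_theta`, `boundary_radius_px`
#'   (angle x frame), `center`).
#' @export
generate_scene <- function(config) {
  validate_scene_config(config)
  with_seed(config$seed, {
    H <- config$image_shape[1]; W <- config$image_shape[2]
    T_ <- config$n_frames
    ctr <- c((H + 1) / 2, (W + 1) / 2)
    rowm <- matrix(seq_len(H), H, W)
    colm <- matrix(seq_len(W), H, W, byrow = TRUE)
    dx <- colm - ctr[2]
    dy <- -(rowm - ctr[1])          # y up, so angles match compass intuition
    theta_px <- atan2(dy, dx)
    rho_px <- sqrt(dx^2 + dy^2)
    ang_prof <- hotspot_angular_profile(theta_px, config$hotspot_angle_deg,
                                        config$hotspot_angular_width_deg)
    t_min <- (seq_len(T_) - 1) * config$frame_interval_min
    pulse <- pulse_waveform(t_min, config$pulse_period_min, config$pulse_shape,
                            config$pulse_duty)
    dr <- config$drift_quadratic_coeffs
    drift <- dr[1] + dr[2] * t_min + dr[3] * t_min^2
    theta_grid <- seq(0, 2 * pi, length.out = 361L)[-361L]

    dim3 <- c(H, W, T_)
    activity <- array(0, dim3); mask <- array(FALSE, dim3)
    donor <- array(0, dim3); fretch <- array(0, dim3); acceptor <- array(0, dim3)
    sens <- array(0, dim3); donor_true <- array(0, dim3); acc_true <- array(0, dim3)
    boundary_radius <- matrix(0, length(theta_grid), T_)

    for (t in seq_len(T_)) {
      jit <- if (config$boundary_motility_amp_px > 0) {
        lapply(1:3, function(m) list(order = m,
                                     amp = config$boundary_motility_amp_px / sqrt(3) * rnorm(1),
                                     phase = runif(1, 0, 2 * pi)))
      } else NULL
      r_px <- scene_radius(theta_px, config, jit)
      m <- rho_px <= r_px
      depth <- r_px - rho_px   # radial depth from the membrane, valid star-convex
      hot <- ang_prof * (depth <= config$hotspot_edge_depth_px)
      E <- config$baseline_activity + drift[t] +
        hot * (config$hotspot_activity + config$pulse_amplitude * pulse[t])
      E[!m] <- 0
      if (any(E >= 1)) stop("rendered activity reached 1; lower the configured levels")
      d_t <- config$donor_expression * (1 - E) * m
      s_t <- config$donor_expression * E * m
      a_t <- config$acceptor_expression * m
      f_t <- s_t + config$alpha_D * d_t + config$alpha_A * a_t
      activity[, , t] <- E; mask[, , t] <- m
      sens[, , t] <- s_t; donor_true[, , t] <- d_t; acc_true[, , t] <- a_t
      donor[, , t] <- add_noise(d_t, config)
      fretch[, , t] <- add_noise(f_t, config)
      acceptor[, , t] <- add_noise(a_t, config)
      boundary_radius[, t] <- scene_radius(theta_grid, config, jit)
    }
    frames <- fret_frameset(donor, fretch, acceptor,
                            pixel_size_um = config$pixel_size_um,
                            frame_interval_min = config$frame_interval_min)
    truth <- structure(list(activity_field = activity, mask_truth = mask,
                            sensitized_truth = sens, donor_truth = donor_true,
                            acceptor_truth = acc_true,
                            boundary_theta = theta_grid,
                            boundary_radius_px = boundary_radius, center = ctr),
                       class = "scene_truth")
    list(frames = frames, truth = truth)
  })
}

#' Generate a pre/post acceptor-photobleaching frame pair
#'
#' Bleaching a fraction b of the acceptor removes the same fraction of the
#' energy transfer: post acceptor = A (1 - b), post sensitized = D E (1 - b),
#' post donor = D (1 - E (1 - b)).  The noise-free pair therefore reproduces
#' the closed-form donor recovery 100 b E / (1 - E + b E) per pixel (100 E at
#' full bleach).
#'
#' @param config a [scene_config()]; frame 1 of the configured scene is used.
#' @param bleach_profile scalar in [0,1] or H x W matrix of bleach fractions.
#' @param dose_label free-text dose tag (e.g. "2X", "5X", "10X").
#' @return `apb_pair`: list with `pre`/`post` (single-frame
#'   [fret_frameset()]s), `bleach_fraction_map`, `dose_label`, and `truth`
#'   (activity/mask of the underlying frame).
#' @export
generate_apb_pair <- function(config, bleach_profile, dose_label = "1X") {
  cfg <- config
  cfg$n_frames <- 1L
  sc <- generate_scene_noisefree_first(cfg)
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
  b <- if (is.matrix(bleach_profile)) bleach_profile else matrix(bleach_profile, H, W)
  if (any(b < 0 | b > 1)) stop("bleach fractions must lie in [0, 1]")
  E <- sc$truth$activity_field[, , 1]
  m <- sc$truth$mask_truth[, , 1]
  D <- cfg$donor_expression; A <- cfg$acceptor_expression
  pre_d <- sc$truth$donor_truth[, , 1]
  pre_a <- sc$truth$acceptor_truth[, , 1]
  pre_f <- sc$truth$sensitized_truth[, , 1] + cfg$alpha_D * pre_d + cfg$alpha_A * pre_a
  post_d <- D * (1 - E * (1 - b)) * m
  post_a <- A * (1 - b) * m
  post_s <- D * E * (1 - b) * m
  post_f <- post_s + cfg$alpha_D * post_d + cfg$alpha_A * post_a
  with_seed(cfg$seed, {
    pre <- fret_frameset(add_noise(pre_d, cfg), add_noise(pre_f, cfg), add_noise(pre_a, cfg),
                         pixel_size_um = cfg$pixel_size_um,
                         frame_interval_min = cfg$frame_interval_min)
    post <- fret_frameset(add_noise(post_d, cfg), add_noise(post_f, cfg), add_noise(post_a, cfg),
                          pixel_size_um = cfg$pixel_size_um,
                          frame_interval_min = cfg$frame_interval_min)
    structure(list(pre = pre, post = post, bleach_fraction_map = b,
                   dose_label = dose_label,
                   truth = list(activity = E, mask = m)),
              class = "apb_pair")
  })
}

# Noise-free single evaluation of the scene truth (shared by the APB pair).
generate_scene_noisefree_first <- function(cfg) {
  cfg$gauss_noise_sd <- 0
  cfg$poisson_like <- FALSE
  generate_scene(cfg)
}

#' Generate a saturable one-site binding table
#'
#' Y = Bmax X / (Kd + X) plus optional Gaussian noise (absolute, or relative
#' to the noise-free value).  Negative draws are clipped at 0 (bound signal is
#' non-negative).
#'
#' @param bmax,kd isotherm parameters (au, nM); both must be positive.
#' @param X ligand concentrations in nM, strictly positive.
#' @param noise_sd Gaussian noise SD (au), or relative SD if `relative = TRUE`.
#' @param relative interpret `noise_sd` as a fraction of the true value.
#' @param n_replicates replicate curves drawn with independent noise.
#' @param seed RNG seed.
#' @return `binding_data` data.frame with columns X, Y, replicate.
#' @export
generate_binding_curve <- function(bmax, kd, X, noise_sd = 0, relative = FALSE,
                                   n_replicates = 1L, seed = NULL) {
  stopifnot(bmax > 0, kd > 0, all(X > 0))
  X <- sort(X)
  y0 <- bmax * X / (kd + X)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
      sdv <- if (relative) noise_sd * y0 else rep(noise_sd, length(X))
      y <- if (noise_sd > 0) pmax(y0 + rnorm(length(X), sd = sdv), 0) else y0
      data.frame(X = X, Y = y, replicate = rep)
    }))
    class(out) <- c("binding_data", "data.frame")
    out
  })
}
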