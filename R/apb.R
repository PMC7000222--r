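#' Donor recovery percentage after acceptor photobleaching
#'
#' recovery = (1 - pre/post) * 100.  Destroying the acceptor abolishes energy
#' transfer, so wherever FRET was occurring the donor brightens and recovery is
#' positive; it is 0 when nothing changed and negative where the donor fell.
#' Non-positive post-bleach intensities give NA (undefined).
#'
#' @param pre,post pre-/post-bleach donor intensities (scalars, vectors or
#'   matrices of matching shape).
#' @return recovery in percent, same shape as the inputs.
#' @export
donor_recovery_percent <- function(pre, post) {
  out <- (1 - pre / post) * 100
  out[post <= 0] <- NA_real_
  out
}

#' Post-minus-pre donor difference image
#'
#' @param pair an `apb_pair` (see [generate_apb_pair()]) or a list with
#'   single-frame `pre`/`post` framesets.
#' @return signed H x W matrix (positive where the donor recovered).
#' @export
delta_donor_image <- function(pair) {
  pre <- frame_of(pair$pre$donor, 1L)
  post <- frame_of(pair$post$donor, 1L)
  if (!identical(dim(pre), dim(post))) stop("pre/post frames are not aligned")
  post - pre
}

# Bilinear interpolation of img at fractional (row, col) coordinates, clamped
# to the image domain.
bilinear_sample <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- img[cbind(r0, c0)];     i01 <- img[cbind(r0, c0 + 1L)]
  i10 <- img[cbind(r0 + 1L, c0)]; i11 <- img[cbind(r0 + 1L, c0 + 1L)]
  i00 * (1 - fr) * (1 - fc) + i01 * (1 - fr) * fc +
    i10 * fr * (1 - fc) + i11 * fr * fc
}

# Unit-step sample coordinates and distances along boundary-to-centroid lines.
# Returns a data-frame-like list pooled over all boundary points.
linescan_samples <- function(boundary, centroid, sampling = c("bilinear", "nearest")) {
  sampling <- match.arg(sampling)
  n <- nrow(boundary)
  rs <- cs <- ds <- vector("list", n)
  for (i in seq_len(n)) {
    p <- boundary[i, ]
    v <- centroid - p
    L <- sqrt(sum(v^2))
    steps <- seq(0, floor(L))
    if (L == 0) steps <- 0
    rs[[i]] <- p[1] + v[1] * steps / max(L, 1e-12)
    cs[[i]] <- p[2] + v[2] * steps / max(L, 1e-12)
    ds[[i]] <- steps
  }
  r <- unlist(rs); c <- unlist(cs)
  if (sampling == "nearest") { r <- round(r); c <- round(c) }
  list(r = r, c = c, dist = unlist(ds), n_lines = n)
}

#' Radial donor-recovery profile from periphery-to-centroid linescans
#'
#' From every boundary pixel of the pre-bleach mask a straight line to the
#' centroid is sampled at unit steps (bilinear interpolation by default).
#' Samples from all lines are pooled into distance-from-periphery bins
#' (arc-length along each line from its boundary endpoint), and the recovery
#' per bin is computed from the bin-mean pre and post intensities — a ratio of
#' means, which is robust at low counts — via
#' [donor_recovery_percent()].
#'
#' @param pair an `apb_pair`.
#' @param mask optional `cell_mask_stack` of the pre-bleach frame; segmented
#'   from the pre-bleach acceptor channel when omitted.
#' @param bin_width_px width of the distance bins.
#' @param sampling `"bilinear"` (default) or `"nearest"` rasterization.
#' @return `recovery_profile`: list with `distance_bin_centers_px`,
#'   `mean_recovery_pct`, `mean_pre`, `mean_post`, `n_samples`, `n_lines`,
#'   `bin_width_px`, `pixel_size_um`, `dose_label`.
#' @export
radial_recovery_profile <- function(pair, mask = NULL, bin_width_px = 1,
                                    sampling = "bilinear") {
  stopifnot(bin_width_px > 0)
  if (is.null(mask)) mask <- build_mask(pair$pre$acceptor)
  m <- mask$masks[, , 1]
  centroid <- mask$centroids[1, ]
  if (!m[round(centroid[1]), round(centroid[2])])
    stop("centroid falls outside the mask; inspect the segmentation")
  boundary <- mask$boundaries[[1]]
  sm <- linescan_samples(boundary, centroid, sampling)
  pre <- frame_of(pair$pre$donor, 1L)
  post <- frame_of(pair$post$donor, 1L)
  pv <- bilinear_sample(pre, sm$r, sm$c)
  qv <- bilinear_sample(post, sm$r, sm$c)
  bin <- floor(sm$dist / bin_width_px) + 1L
  nb <- max(bin)
  sum_pre <- vapply(seq_len(nb), function(b) sum(pv[bin == b]), numeric(1))
  sum_post <- vapply(seq_len(nb), function(b) sum(qv[bin == b]), numeric(1))
  cnt <- tabulate(bin, nb)
  keep <- cnt > 0L
  rec <- donor_recovery_percent(sum_pre[keep] / cnt[keep], sum_post[keep] / cnt[keep])
  structure(list(distance_bin_centers_px = ((seq_len(nb) - 0.5) * bin_width_px)[keep],
                 mean_recovery_pct = rec,
                 mean_pre = (sum_pre / cnt)[keep],
                 mean_post = (sum_post / cnt)[keep],
                 n_samples = cnt[keep],
                 n_lines = sm$n_lines,
                 bin_width_px = bin_width_px,
                 pixel_size_um = pair$pre$pixel_size_um,
                 dose_label = pair$dose_label),
            class = "recovery_profile")
}

#' Peripheral recovery summary across bleach doses
#'
#' Mean recovery over the bins whose centers lie within `band_px` of the cell
#' edge, per dose label — the quantity plotted against bleaching light dosage.
#'
#' @param profiles a `recovery_profile` or list of them.
#' @param band_px distance band from the periphery, in pixels.
#' @return data.frame with columns `dose_label`, `mean_recovery_pct`, `n_bins`.
#' @export
peripheral_recovery_summary <- function(profiles, band_px) {
  if (inherits(profiles, "recovery_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    sel <- p$distance_bin_centers_px <= band_px
    if (!any(sel)) stop("band contains no bins; widen band_px")
    data.frame(dose_label = p$dose_label,
               mean_recovery_pct = mean(p$mean_recovery_pct[sel]),
               n_bins = sum(sel))
  })
  do.call(rbind, rows)
}
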