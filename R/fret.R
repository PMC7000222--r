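#' Aligned three-channel intensity time-lapse
#'
#' Container for the donor (Dex-Dem), raw FRET (Dex-Aem) and acceptor
#' (Aex-Aem) stacks plus acquisition metadata.  All three stacks must share
#' the same H x W x T shape.
#'
#' @param donor,fret,acceptor H x W x T arrays (or matrices for T = 1).
#' @param pixel_size_um,frame_interval_min acquisition metadata.
#' @return `fret_frameset` list.
#' @export
fret_frameset <- function(donor, fret, acceptor,
                          pixel_size_um = 0.2, frame_interval_min = 0.5) {
  plain <- function(x) { a <- as_stack(x); attributes(a) <- list(dim = dim(a)); a }
  donor <- plain(donor); fret <- plain(fret); acceptor <- plain(acceptor)
  if (!identical(dim(donor), dim(fret)) || !identical(dim(donor), dim(acceptor)))
    stop("channel stacks must share the same dimensions")
  if (anyNA(donor) || anyNA(fret) || anyNA(acceptor))
    stop("channel stacks must be finite")
  stopifnot(pixel_size_um > 0, frame_interval_min > 0)
  structure(list(donor = donor, fret = fret, acceptor = acceptor,
                 pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min),
            class = "fret_frameset")
}

#' Bleed-through coefficients
#'
#' @param alpha_D donor emission leaking into the FRET detection band.
#' @param alpha_A acceptor directly excited by the donor laser.
#' @return `bleedthrough_coefficients` list.
#' @export
bleedthrough_coefficients <- function(alpha_D = 0.55, alpha_A = 0.028) {
  if (alpha_D < 0 || alpha_D >= 1 || alpha_A < 0 || alpha_A >= 1)
    stop("bleed-through slopes must lie in [0, 1)")
  structure(list(alpha_D = alpha_D, alpha_A = alpha_A),
            class = "bleedthrough_coefficients")
}

#' Estimate a bleed-through slope from a single-label sample
#'
#' For a donor-only sample the Dex-Aem channel contains only donor
#' bleed-through, so the slope of Dex-Aem against Dex-Dem through the origin
#' over masked pixels estimates alpha_D; analogously Dex-Aem against Aex-Aem
#' estimates alpha_A on acceptor-only samples.  Pixels are pooled across
#' frames of one cell; when several cells (framesets) are supplied as a list,
#' per-cell slopes are averaged.
#'
#' @param single_label_set a [fret_frameset()] imaged with only the named
#'   fluorophore, or a list of them.
#' @param which `"donor"` or `"acceptor"`.
#' @param mask a `cell_mask_stack` or logical array selecting cell pixels.
#' @return scalar slope estimate.
#' @export
estimate_bleedthrough <- function(single_label_set, which = c("donor", "acceptor"),
                                  mask) {
  which <- match.arg(which)
  if (inherits(single_label_set, "fret_frameset")) {
    single_label_set <- list(single_label_set)
    mask <- list(mask)
  }
  slopes <- mapply(function(fs, mk) {
    mm <- if (inherits(mk, "cell_mask_stack")) mk$masks else as_stack(mk) > 0
    if (!any(mm)) stop("empty mask: cannot calibrate bleed-through")
    x <- if (which == "donor") fs$donor[mm] else fs$acceptor[mm]
    y <- fs$fret[mm]
    sxx <- sum(x * x)
    if (sxx <= 0) stop("zero-variance predictor: cannot calibrate bleed-through")
    sum(x * y) / sxx
  }, single_label_set, mask)
  mean(slopes)
}

# 2x2 block median, top-left anchored with edge replication: out[r, c] is the
# median of in[r..r+1, c..c+1]; the median of four values is the mean of the
# two central ones.
median_filter_2x2 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  a <- m
  b <- m[, c(seq_len(W)[-1], W)]
  cc <- m[c(seq_len(H)[-1], H), ]
  d <- m[c(seq_len(H)[-1], H), c(seq_len(W)[-1], W)]
  s <- a + b + cc + d
  mx <- pmax(a, b, cc, d)
  mn <- pmin(a, b, cc, d)
  (s - mx - mn) / 2
}

#' Compute the bleed-through-corrected FRET-index image
#'
#' FRET index = I_FRET - alpha_D I_Donor - alpha_A I_Acceptor, pixel-wise,
#' optionally followed by a 2 x 2 block median filter per frame (top-left
#' anchor, edge replication).  Negative values are retained in the float
#' output; they are clipped only on 8-bit export ([to_8bit()]).
#'
#' @param frames a [fret_frameset()].
#' @param coeffs [bleedthrough_coefficients()].
#' @param median_filter apply the 2 x 2 median filter.
#' @return H x W x T numeric array (the FRET_T stack).
#' @export
compute_fret_index <- function(frames, coeffs = bleedthrough_coefficients(),
                               median_filter = FALSE) {
  stopifnot(inherits(frames, "fret_frameset"))
  out <- frames$fret - coeffs$alpha_D * frames$donor - coeffs$alpha_A * frames$acceptor
  if (median_filter)
    for (t in seq_len(dim(out)[3])) out[, , t] <- median_filter_2x2(out[, , t])
  out
}

#' Donor-normalized FRET
#'
#' FRET_T divided by the donor fluorescence, pixel-wise inside the mask;
#' normalizes activity for sensor expression.  Pixels with donor below `floor`
#' (and all pixels outside the mask) are NA and excluded from downstream means.
#'
#' @param fret_index H x W x T array from [compute_fret_index()].
#' @param donor matching donor stack.
#' @param mask `cell_mask_stack` or logical array.
#' @param floor positive donor threshold below which the ratio is undefined.
#' @return H x W x T array with NA outside the defined domain.
#' @export
donor_normalized_fret <- function(fret_index, donor, mask, floor = 1) {
  stopifnot(floor > 0)
  fret_index <- as_stack(fret_index); donor <- as_stack(donor)
  if (!identical(dim(fret_index), dim(donor))) stop("shape mismatch")
  mm <- if (inherits(mask, "cell_mask_stack")) mask$masks else as_stack(mask) > 0
  out <- fret_index / donor
  out[!mm | donor < floor] <- NA_real_
  out
}

#' Spectral FRET efficiency
#'
#' Fa / (Fa + Fd) from raw acceptor and donor emission intensities; lies in
#' [0, 1] and increases monotonically with the sensitized acceptor emission.
#'
#' @param Fa,Fd non-negative acceptor/donor raw emission (vectors allowed).
#' @return efficiency in [0, 1].
#' @export
fret_efficiency <- function(Fa, Fd) {
  if (any(Fa < 0) || any(Fd < 0)) stop("raw emission intensities must be non-negative")
  if (any(Fa + Fd <= 0)) stop("Fa + Fd must be positive for a defined ratio")
  Fa / (Fa + Fd)
}

#' Convert a float stack to 8-bit
#'
#' Affine map to 0..255 with rounding half-up.  `"global-minmax"` scales the
#' global range of the stack (a constant stack maps to all zeros);
#' `"fixed-range"` uses the supplied [lo, hi] window and clips.
#'
#' @param stack numeric array or matrix, finite.
#' @param mode `"global-minmax"` or `"fixed-range"`.
#' @param lo,hi window for `"fixed-range"`.
#' @return integer array of the same shape with values in 0..255.
#' @export
to_8bit <- function(stack, mode = c("global-minmax", "fixed-range"),
                    lo = 0, hi = 255) {
  mode <- match.arg(mode)
  if (anyNA(stack) || any(!is.finite(stack))) stop("stack must be finite")
  if (mode == "global-minmax") {
    lo <- min(stack); hi <- max(stack)
    if (hi <= lo) {
      out <- stack; out[] <- 0L; storage.mode(out) <- "integer"
      return(out)
    }
  } else if (hi <= lo) stop("fixed range requires hi > lo")
  sc <- (stack - lo) / (hi - lo) * 255
  out <- floor(pmin(pmax(sc, 0), 255) + 0.5)
  out <- pmin(out, 255)
  storage.mode(out) <- "integer"
  out
}
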