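#' Otsu threshold of an intensity image
#'
#' Histogram-based threshold maximizing between-class variance, the usual
#' automatic stand-in for the user-chosen global threshold applied to the
#' acceptor channel before mask generation.
#'
#' @param x numeric matrix or array of intensities.
#' @param n_bins number of histogram bins.
#' @return scalar threshold on the intensity scale of `x`; pixels strictly
#'   above it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite intensities")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(n_bins, 1L + floor((v - lo) / (hi - lo) * n_bins)), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  lo + k * (hi - lo) / n_bins
}

#' Label connected components of a binary image
#'
#' Run-length two-pass labeling with union-find; labels are 1..k in first-pixel
#' raster order, 0 for background.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  H <- nrow(mask); W <- ncol(mask)
  labels <- matrix(0L, H, W)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pad <- if (connectivity == 8L) 1L else 0L
  prev_s <- integer(0); prev_e <- integer(0); prev_id <- integer(0)
  run_rows <- list()
  for (r in seq_len(H)) {
    row <- mask[r, ]
    rl <- rle(as.logical(row))
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    fg <- which(rl$values)
    cur_s <- starts[fg]; cur_e <- ends[fg]
    cur_id <- integer(length(fg))
    for (j in seq_along(fg)) {
      s <- cur_s[j]; e <- cur_e[j]
      hit <- which(prev_e >= s - pad & prev_s <= e + pad)
      if (!length(hit)) {
        parent[length(parent) + 1L] <- length(parent) + 1L
        cur_id[j] <- length(parent)
      } else {
        roots <- vapply(prev_id[hit], find, integer(1))
        keep <- min(roots)
        for (rt in roots) if (rt != keep) parent[rt] <- keep
        cur_id[j] <- keep
      }
    }
    run_rows[[r]] <- list(s = cur_s, e = cur_e, id = cur_id)
    prev_s <- cur_s; prev_e <- cur_e; prev_id <- cur_id
  }
  if (!length(parent)) return(labels)
  roots <- vapply(seq_along(parent), find, integer(1))
  relab <- integer(length(parent))
  nxt <- 0L
  for (r in seq_len(H)) {
    rr <- run_rows[[r]]
    for (j in seq_along(rr$id)) {
      rt <- roots[rr$id[j]]
      if (relab[rt] == 0L) { nxt <- nxt + 1L; relab[rt] <- nxt }
      labels[r, rr$s[j]:rr$e[j]] <- relab[rt]
    }
  }
  labels
}

#' Fill holes in a binary mask
#'
#' Background regions (4-connected) not touching the image border become
#' foreground, mirroring the hole-filling step of the mask pipeline.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
fill_holes <- function(mask) {
  lb <- label_components(!mask, connectivity = 4L)
  border <- unique(c(lb[1, ], lb[nrow(lb), ], lb[, 1], lb[, ncol(lb)]))
  border <- border[border > 0L]
  mask | (lb > 0L & !(lb %in% border))
}

#' Remove small connected components
#'
#' @param mask logical matrix.
#' @param min_area_px components strictly smaller than this are dropped.
#' @param connectivity 4 or 8.
#' @return logical matrix.
#' @export
remove_small_components <- function(mask, min_area_px, connectivity = 8L) {
  lb <- label_components(mask, connectivity)
  if (!any(lb > 0L)) return(mask & FALSE)
  sz <- tabulate(lb[lb > 0L])
  keep <- which(sz >= min_area_px)
  matrix(lb %in% keep, nrow(mask), ncol(mask))
}

# 1-D squared Euclidean distance transform (lower envelope of parabolas).
dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance to the nearest background pixel
#'
#' Exact Euclidean distance transform (Felzenszwalb-Huttenlocher): for every
#' foreground pixel, the distance in pixels to the nearest background pixel
#' center; 0 on background.  This is the "distance from the periphery" field
#' used by erosion and available as an alternative linescan coordinate.
#'
#' @param mask logical matrix (TRUE = inside the cell).
#' @return numeric matrix of distances in pixels.
#' @export
edge_distance <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(!mask)) stop("mask has no background; distance undefined")
  H <- nrow(mask); W <- ncol(mask)
  big <- (H * H + W * W) * 4
  f <- matrix(0, H, W)
  f[mask] <- big
  for (r in seq_len(H)) f[r, ] <- dt1d(f[r, ])
  for (cc in seq_len(W)) f[, cc] <- dt1d(f[, cc])
  sqrt(f)
}

#' Binary erosion by a Euclidean disk
#'
#' A pixel survives when its distance to the background exceeds the radius,
#' i.e. the whole disk of that radius fits inside the foreground.
#'
#' @param mask logical matrix.
#' @param radius_px disk radius in pixels; radius <= 0 is a no-op.
#' @return logical matrix.
#' @export
erode_mask <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  edge_distance(mask) > radius_px
}
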