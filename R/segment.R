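#' Trace the ordered outer boundary of a connected mask
#'
#' Moore-neighbor tracing with Jacob's stopping criterion.  The walk starts at
#' the topmost-leftmost foreground pixel and proceeds clockwise, yielding a
#' closed 8-connected loop (closure between last and first point is implicit).
#' A single isolated pixel returns a 1-row matrix with attribute
#' `degenerate = TRUE`.
#'
#' @param mask logical matrix containing one connected foreground component.
#' @return n x 2 integer matrix of (row, col) boundary pixels, ordered.
#' @export
trace_boundary <- function(mask) {
  stopifnot(is.matrix(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask: nothing to trace")
  o <- order(idx[, 1], idx[, 2])
  s <- as.integer(idx[o[1], ])
  # neighbor offsets, clockwise starting from West
  nb <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                 0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L), ncol = 2, byrow = TRUE)
  H <- nrow(mask); W <- ncol(mask)
  is_fg <- function(r, c) r >= 1L && r <= H && c >= 1L && c <= W && mask[r, c]
  pts <- vector("list", 64L)
  np <- 1L; pts[[1L]] <- s
  p <- s; bdir <- 1L
  first_state <- NULL
  for (iter in seq_len(8L * H * W)) {
    dir <- 0L
    for (k in 1:8) {
      d <- ((bdir - 1L + k) %% 8L) + 1L
      if (is_fg(p[1] + nb[d, 1], p[2] + nb[d, 2])) { dir <- d; break }
    }
    if (dir == 0L) {  # isolated pixel
      out <- matrix(s, 1, 2, dimnames = list(NULL, c("row", "col")))
      attr(out, "degenerate") <- TRUE
      return(out)
    }
    prev_dir <- ((dir - 2L) %% 8L) + 1L
    bcell <- c(p[1] + nb[prev_dir, 1], p[2] + nb[prev_dir, 2])
    p <- c(p[1] + nb[dir, 1], p[2] + nb[dir, 2])
    dd <- bcell - p
    bdir <- which(nb[, 1] == dd[1] & nb[, 2] == dd[2])
    state <- c(p, bdir)
    if (!is.null(first_state) && all(state == first_state)) break
    if (is.null(first_state)) first_state <- state
    np <- np + 1L
    if (np > length(pts)) pts <- c(pts, vector("list", length(pts)))
    pts[[np]] <- p
  }
  out <- do.call(rbind, pts[seq_len(np)])
  colnames(out) <- c("row", "col")
  out
}

#' Chain length of a closed boundary
#'
#' Sum of step lengths along the loop (diagonal steps weighted sqrt(2)),
#' including the implicit closing step.  `corrected = TRUE` applies Kulpa's
#' factor 0.948, the standard compensation for the overestimation of smooth
#' perimeters by 8-connected chain codes.
#'
#' @param boundary n x 2 matrix from [trace_boundary()].
#' @param corrected apply the Kulpa perimeter correction.
#' @return length in pixels.
#' @export
chain_length <- function(boundary, corrected = FALSE) {
  n <- nrow(boundary)
  if (n < 2L) return(0)
  nxt <- rbind(boundary[-1, , drop = FALSE], boundary[1, , drop = FALSE])
  dr <- abs(nxt[, 1] - boundary[, 1])
  dc <- abs(nxt[, 2] - boundary[, 2])
  len <- sum(ifelse(dr + dc == 2L, sqrt(2), 1)[dr + dc > 0L])
  if (corrected) 0.948 * len else len
}

#' Segment the cell footprint in every frame
#'
#' Mask pipeline: global threshold (Otsu by default), optional erosion
#' smoothing, hole filling, small-particle removal, then selection of a single
#' component per frame (largest in the first frame, nearest-centroid linkage
#' afterwards).  Centroid is the mean of foreground pixel coordinates.
#'
#' @param acceptor H x W x T array (or matrix) of acceptor-channel intensities.
#' @param threshold `"otsu"` or a fixed numeric threshold; pixels strictly
#'   above threshold are foreground.
#' @param min_area_px components smaller than this are discarded.
#' @param erosion_radius_px disk radius for the smoothing erosion (0 disables;
#'   the default, appropriate for low-noise data — enable for noisy movies).
#' @param pixel_size_um pixel size carried as metadata.
#' @return `cell_mask_stack`: list with `masks` (H x W x T logical),
#'   `centroids` (T x 2, row/col), `boundaries` (list of ordered loops),
#'   `areas_px2`, `pixel_size_um`.
#' @export
build_mask <- function(acceptor, threshold = "otsu", min_area_px = 50,
                       erosion_radius_px = 0, pixel_size_um = 0.2) {
  stk <- as_stack(acceptor)
  T_ <- dim(stk)[3]
  masks <- array(FALSE, dim(stk))
  centroids <- matrix(NA_real_, T_, 2, dimnames = list(NULL, c("row", "col")))
  boundaries <- vector("list", T_)
  areas <- numeric(T_)
  prev_centroid <- NULL
  for (t in seq_len(T_)) {
    fr <- stk[, , t]
    thr <- if (identical(threshold, "otsu")) otsu_threshold(fr) else as.numeric(threshold)
    m <- fr > thr
    if (!any(m)) stop(sprintf("no cell detected in frame %d (empty after threshold)", t))
    m <- erode_mask(m, erosion_radius_px)
    if (any(m)) m <- fill_holes(m)
    m <- remove_small_components(m, min_area_px)
    lb <- label_components(m)
    k <- max(lb)
    if (k == 0L) stop(sprintf("no cell detected in frame %d (empty after filtering)", t))
    if (k > 1L) {
      cents <- lapply(seq_len(k), function(i) colMeans(which(lb == i, arr.ind = TRUE)))
      if (is.null(prev_centroid)) {
        sz <- tabulate(lb[lb > 0L], k)
        pick <- which.max(sz)
      } else {
        d2 <- vapply(cents, function(ce) sum((ce - prev_centroid)^2), numeric(1))
        pick <- which.min(d2)
      }
      m <- lb == pick
    }
    cc <- colMeans(which(m, arr.ind = TRUE))
    masks[, , t] <- m
    centroids[t, ] <- cc
    boundaries[[t]] <- trace_boundary(m)
    areas[t] <- sum(m)
    prev_centroid <- cc
  }
  structure(list(masks = masks, centroids = centroids, boundaries = boundaries,
                 areas_px2 = areas, pixel_size_um = pixel_size_um),
            class = "cell_mask_stack")
}

#' Detect the ordered cell boundary of a single frame
#'
#' Either traces a binary mask directly, or runs Canny edge detection on an
#' intensity image and reconciles the edge map to the outermost closed contour
#' (edge loop filled, largest component traced).  On clean masks the two
#' methods agree to within one pixel.
#'
#' @param x logical mask (`method = "mask-trace"`) or intensity matrix
#'   (`method = "canny"`).
#' @param method `"mask-trace"` or `"canny"`.
#' @param sigma,low,high Canny parameters, see [canny_edges()].
#' @return ordered boundary matrix as in [trace_boundary()].
#' @export
detect_boundary <- function(x, method = c("mask-trace", "canny"),
                            sigma = 2, low = 0.1, high = 0.3) {
  method <- match.arg(method)
  if (method == "mask-trace") {
    stopifnot(is.logical(x) || all(x %in% c(0, 1)))
    return(trace_boundary(x > 0))
  }
  e <- canny_edges(x, sigma, low, high)
  if (!any(e)) stop("no edges detected")
  filled <- fill_holes(e)
  lb <- label_components(filled)
  sz <- tabulate(lb[lb > 0L])
  trace_boundary(lb == which.max(sz))
}

#' Axis-aligned quadrant labels around the per-frame centroid
#'
#' A vertical and a horizontal line through the centroid split the mask into
#' quadrants Q1 = top-left, Q2 = top-right, Q3 = bottom-left, Q4 =
#' bottom-right (image orientation: row increases downwards).  Pixels exactly
#' on a dividing line are assigned to the right/bottom side.
#'
#' @param mask_stack a `cell_mask_stack`.
#' @return integer array H x W x T, 0 outside, 1..4 inside.
#' @export
quadrant_labels <- function(mask_stack) {
  stopifnot(inherits(mask_stack, "cell_mask_stack"))
  dm <- dim(mask_stack$masks)
  labels <- array(0L, dm)
  rowm <- matrix(seq_len(dm[1]), dm[1], dm[2])
  colm <- matrix(seq_len(dm[2]), dm[1], dm[2], byrow = TRUE)
  for (t in seq_len(dm[3])) {
    ce <- mask_stack$centroids[t, ]
    top <- rowm < ce[1]
    left <- colm < ce[2]
    q <- 1L + (!left) + 2L * (!top)
    q[!mask_stack$masks[, , t]] <- 0L
    labels[, , t] <- q
  }
  labels
}
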