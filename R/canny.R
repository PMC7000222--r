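# Canny edge detection: Gaussian smoothing, Sobel gradients, non-maximum
# suppression and hysteresis linking.  Thresholds are fractions of the maximum
# gradient magnitude (the image scale is arbitrary fluorescence units).

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with edge replication.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  H <- nrow(img); W <- ncol(img)
  pad_r <- img[c(rep(1L, r), seq_len(H), rep(H, r)), , drop = FALSE]
  tmp <- matrix(0, H, W)
  for (i in seq_along(k)) tmp <- tmp + k[i] * pad_r[(i - 1L) + seq_len(H), , drop = FALSE]
  pad_c <- tmp[, c(rep(1L, r), seq_len(W), rep(W, r)), drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * pad_c[, (i - 1L) + seq_len(W), drop = FALSE]
  out
}

sobel_gradients <- function(img) {
  gx <- shift_mat(img, 0, -1) - shift_mat(img, 0, 1)
  gy <- shift_mat(img, -1, 0) - shift_mat(img, 1, 0)
  sx <- 2 * gx + shift_mat(gx, -1, 0) + shift_mat(gx, 1, 0)
  sy <- 2 * gy + shift_mat(gy, 0, -1) + shift_mat(gy, 0, 1)
  list(gx = sx, gy = sy, mag = sqrt(sx^2 + sy^2))
}

#' Canny edge map
#'
#' @param img numeric matrix.
#' @param sigma Gaussian smoothing scale in pixels.
#' @param low,high hysteresis thresholds as fractions of the maximum gradient
#'   magnitude after smoothing.
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(img, sigma = 2, low = 0.1, high = 0.3) {
  stopifnot(is.matrix(img), low <= high)
  sm <- gaussian_blur(img, sigma)
  g <- sobel_gradients(sm)
  mag <- g$mag
  # quantize gradient direction to 4 bins and suppress non-maxima
  ang <- atan2(g$gy, g$gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  bin <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, nrow(img), ncol(img))
  for (b in 0:3) {
    d <- off[[b + 1L]]
    n1 <- shift_mat(mag, d[1], d[2])
    n2 <- shift_mat(mag, -d[1], -d[2])
    keep <- keep | (bin == b & mag >= n1 & mag >= n2)
  }
  m <- max(mag)
  if (m <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  strong <- keep & mag >= high * m
  cand <- keep & mag >= low * m
  if (!any(strong)) return(strong)
  lb <- label_components(cand, 8L)
  good <- unique(lb[strong])
  cand & matrix(lb %in% good, nrow(img), ncol(img))
}
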