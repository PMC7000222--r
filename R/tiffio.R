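# Minimal baseline TIFF 6.0 reader/writer for single-channel multi-page
# grayscale stacks (uncompressed, uint8 / uint16 / float32).  No TIFF package
# is available in the target environment, so the subset the pipeline needs is
# implemented here; it is not a general TIFF library.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

#' Write an intensity stack as a multi-page TIFF
#'
#' Uncompressed, grayscale, little-endian; one page per frame.  A YAML sidecar
#' `<path>.yaml` records pixel size and frame interval.
#'
#' @param stack H x W x T numeric array (or matrix).
#' @param path output file path.
#' @param bit_depth `"float32"` (lossless for float32 data) or `"uint8"`.
#' @param pixel_size_um,frame_interval_min metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bit_depth = c("float32", "uint8"),
                        pixel_size_um = 0.2, frame_interval_min = 0.5) {
  bit_depth <- match.arg(bit_depth)
  stk <- as_stack(stack)
  H <- dim(stk)[1]; W <- dim(stk)[2]; T_ <- dim(stk)[3]
  bps <- if (bit_depth == "float32") 32L else 8L
  fmt <- if (bit_depth == "float32") 3L else 1L
  bytes_px <- bps %/% 8L
  strip_bytes <- H * W * bytes_px
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  # layout per page: [pixel data][IFD]; first IFD offset points past page 1 data
  ifd_entries <- 10L
  ifd_size <- 2L + ifd_entries * 12L + 4L
  page_size <- strip_bytes + ifd_size
  first_ifd <- 8L + strip_bytes
  writeBin(first_ifd, con, size = 4, endian = "little")
  wr_entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  for (t in seq_len(T_)) {
    fr <- t(stk[, , t])  # TIFF is row-major
    if (bit_depth == "float32") {
      writeBin(as.numeric(fr), con, size = 4, endian = "little")
    } else {
      v <- as.integer(pmin(pmax(round(fr), 0), 255))
      writeBin(as.raw(v), con)
    }
    data_off <- 8L + (t - 1L) * page_size
    next_ifd <- if (t < T_) data_off + page_size + strip_bytes else 0L
    writeBin(ifd_entries, con, size = 2, endian = "little")
    wr_entry(256, 4, 1, W)
    wr_entry(257, 4, 1, H)
    wr_entry(258, 3, 1, bps)
    wr_entry(259, 3, 1, 1)       # no compression
    wr_entry(262, 3, 1, 1)       # BlackIsZero
    wr_entry(273, 4, 1, data_off)
    wr_entry(277, 3, 1, 1)
    wr_entry(278, 4, 1, H)
    wr_entry(279, 4, 1, strip_bytes)
    wr_entry(339, 3, 1, fmt)
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  meta <- list(pixel_size_um = pixel_size_um, frame_interval_min = frame_interval_min,
               bit_depth = bit_depth, shape = c(H, W, T_))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

read_u16 <- function(raw, off, endian) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2, signed = FALSE, endian = endian)
}
read_u32 <- function(raw, off, endian) {
  v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
  if (v < 0) v <- v + 2^32
  v
}

#' Read a single-channel multi-page TIFF
#'
#' Supports uncompressed grayscale pages (uint8/uint16/float32), both byte
#' orders, multiple strips.  Metadata is taken from the `<path>.yaml` sidecar
#' when present, from arguments otherwise; missing metadata falls back to
#' 0.2 um/px and 0.5 min/frame with a warning.
#'
#' @param path TIFF path.
#' @param pixel_size_um,frame_interval_min metadata overrides.
#' @return H x W x T numeric array with attributes `pixel_size_um` and
#'   `frame_interval_min`.
#' @export
read_stack <- function(path, pixel_size_um = NULL, frame_interval_min = NULL) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("unreadable file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop("not a TIFF file: ", path)
  if (read_u16(raw, 2, endian) != 42L) stop("not a TIFF file: ", path)
  ifd_off <- read_u32(raw, 4, endian)
  pages <- list()
  while (ifd_off != 0) {
    n <- read_u16(raw, ifd_off, endian)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- read_u16(raw, e, endian)
      type <- read_u16(raw, e + 2, endian)
      count <- read_u32(raw, e + 4, endian)
      size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)[type]
      nbytes <- size * count
      val_off <- if (nbytes <= 4) e + 8 else read_u32(raw, e + 8, endian)
      vals <- if (type %in% c(3L)) {
        vapply(seq_len(count) - 1L, function(k) read_u16(raw, val_off + 2 * k, endian), numeric(1))
      } else if (type %in% c(4L)) {
        vapply(seq_len(count) - 1L, function(k) read_u32(raw, val_off + 4 * k, endian), numeric(1))
      } else NULL
      if (!is.null(vals)) tags[[as.character(tag)]] <- vals
    }
    pages[[length(pages) + 1L]] <- tags
    ifd_off <- read_u32(raw, ifd_off + 2 + n * 12, endian)
    if (length(pages) > 1e5) stop("corrupt TIFF: IFD loop")
  }
  get1 <- function(tg, key, default = NULL) {
    v <- tg[[as.character(TIFF_TAGS[[key]])]]
    if (is.null(v)) default else v
  }
  frames <- lapply(pages, function(tg) {
    W <- get1(tg, "ImageWidth"); H <- get1(tg, "ImageLength")
    if (is.null(W) || is.null(H)) stop("TIFF page missing dimensions")
    if (get1(tg, "Compression", 1) != 1) stop("compressed TIFF not supported")
    if (get1(tg, "SamplesPerPixel", 1) != 1) stop("single-channel expected")
    bps <- get1(tg, "BitsPerSample", 8)
    fmt <- get1(tg, "SampleFormat", 1)
    offs <- get1(tg, "StripOffsets")
    cnts <- get1(tg, "StripByteCounts", H * W * bps / 8)
    buf <- unlist(lapply(seq_along(offs), function(i)
      raw[(offs[i] + 1):(offs[i] + cnts[i])]), use.names = FALSE)
    vals <- if (fmt == 3 && bps == 32) {
      readBin(buf, "double", n = H * W, size = 4, endian = endian)
    } else if (bps == 8) {
      as.numeric(readBin(buf, "integer", n = H * W, size = 1, signed = FALSE, endian = endian))
    } else if (bps == 16) {
      as.numeric(readBin(buf, "integer", n = H * W, size = 2, signed = FALSE, endian = endian))
    } else stop(sprintf("unsupported TIFF sample: %d bits, format %d", bps, fmt))
    t(matrix(vals, W, H))  # stored row-major
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF pages have mismatched shapes")
  out <- array(unlist(frames, use.names = FALSE), c(dims[1, 1], dims[2, 1], length(frames)))
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  px <- pixel_size_um %||% meta$pixel_size_um
  fi <- frame_interval_min %||% meta$frame_interval_min
  if (is.null(px) || is.null(fi)) {
    warning("missing metadata; using defaults 0.2 um/px, 0.5 min/frame where absent")
    px <- px %||% 0.2
    fi <- fi %||% 0.5
  }
  attr(out, "pixel_size_um") <- px
  attr(out, "frame_interval_min") <- fi
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the three channels of a frameset as TIFFs
#'
#' Files are named `<prefix>_donor.tif`, `<prefix>_fret.tif`,
#' `<prefix>_acceptor.tif`.
#'
#' @param frames a [fret_frameset()].
#' @param prefix output path prefix.
#' @return named character vector of paths, invisibly.
#' @export
write_frameset <- function(frames, prefix) {
  stopifnot(inherits(frames, "fret_frameset"))
  paths <- c(donor = paste0(prefix, "_donor.tif"),
             fret = paste0(prefix, "_fret.tif"),
             acceptor = paste0(prefix, "_acceptor.tif"))
  for (ch in names(paths))
    write_stack(frames[[ch]], paths[[ch]],
                pixel_size_um = frames$pixel_size_um,
                frame_interval_min = frames$frame_interval_min)
  invisible(paths)
}

#' Read a three-channel frameset written by [write_frameset()]
#'
#' @param prefix path prefix used at write time.
#' @return a [fret_frameset()].
#' @export
read_frameset <- function(prefix) {
  d <- read_stack(paste0(prefix, "_donor.tif"))
  f <- read_stack(paste0(prefix, "_fret.tif"))
  a <- read_stack(paste0(prefix, "_acceptor.tif"))
  fret_frameset(d, f, a, pixel_size_um = attr(d, "pixel_size_um"),
                frame_interval_min = attr(d, "frame_interval_min"))
}
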