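# Image and label-mask I/O with explicit, bit-exact conventions.
#
# Conventions used throughout the package:
#   * images and masks are plain R matrices, rows = image rows (height),
#     columns = image columns (width); origin top-left.
#   * intensity values are kept on their native scale (no range rescaling
#     at load time); multi-channel inputs are reduced to one channel by an
#     unweighted channel mean (microscopy channels are not photometric RGB).
#   * label masks are integer matrices, 0 = background, each cell one
#     positive label; labels need not be contiguous.

img_ext <- function(path) tolower(tools::file_ext(path))

#' Load a microscopy image
#'
#' Reads a TIFF or PNG image (8/16-bit integer or float, 1 or 3 channels)
#' into a numeric matrix on its native intensity scale. Three-channel
#' images are averaged (equal weights) into a single channel; no range
#' rescaling is performed, so a 16-bit image containing 65535 loads as
#' 65535.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A numeric matrix (rows x cols) with attribute `source_dtype`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- img_ext(path)
  if (ext %in% c("tif", "tiff")) {
    is_float <- tryCatch(tiff_sample_format(path) == 3L,
                         error = function(e) FALSE)
    x <- tryCatch({
      # as.is returns native integer values but rejects float samples,
      # which readTIFF already hands back unscaled
      if (is_float) tiff::readTIFF(path) else tiff::readTIFF(path, as.is = TRUE)
    }, error = function(e) stop("unreadable TIFF: ", path, " (",
                                conditionMessage(e), ")"))
    dtype <- if (is_float) "float" else "integer"
  } else if (ext == "png") {
    x <- tryCatch(png::readPNG(path, info = TRUE),
                  error = function(e) stop("unreadable PNG: ", path, " (",
                                           conditionMessage(e), ")"))
    depth <- attr(x, "info")$bit.depth
    if (is.null(depth)) depth <- 8
    x <- x * (2^depth - 1)  # undo readPNG's [0,1] scaling: native integers
    attr(x, "info") <- NULL
    dtype <- paste0("uint", depth)
  } else {
    stop("unsupported image format: ", ext)
  }
  x <- reduce_gray(x)
  if (!all(is.finite(x))) stop("image contains non-finite values: ", path)
  storage.mode(x) <- "double"
  attr(x, "source_dtype") <- dtype
  x
}

# Collapse a (h, w, ch) array to a single channel by the unweighted mean.
# Idempotent on matrices / single-channel arrays.
reduce_gray <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) == 2L) return(matrix(x, d[1], d[2]))
  if (length(d) != 3L) stop("unsupported image shape: ", paste(d, collapse = "x"))
  if (d[3] == 1L) return(x[, , 1L])
  if (d[3] != 3L) stop("unsupported channel count: ", d[3],
                       " (expected 1 or 3)")
  (x[, , 1L] + x[, , 2L] + x[, , 3L]) / 3
}

#' Load an instance label mask
#'
#' Reads an integer-typed TIFF or PNG label mask. Values are preserved
#' exactly; 0 is background and each positive integer is one cell (labels
#' need not be contiguous). Float-typed TIFF input is rejected because
#' labels must be exact.
#'
#' @param path Path to the mask file.
#' @return An integer matrix.
#' @export
load_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- img_ext(path)
  if (ext %in% c("tif", "tiff")) {
    if (tiff_sample_format(path) == 3L)
      stop("label mask must be integer-typed, got float samples: ", path)
    x <- tiff::readTIFF(path, as.is = TRUE)
    if (!is.integer(x))
      stop("label mask must be integer-typed: ", path)
  } else if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    depth <- attr(x, "info")$bit.depth
    if (is.null(depth)) depth <- 8
    x <- round(x * (2^depth - 1))
  } else {
    stop("unsupported mask format: ", ext)
  }
  x <- as.matrix(x)
  if (length(dim(x)) != 2L) stop("label mask must be single-channel: ", path)
  if (any(x < 0)) stop("label mask contains negative values: ", path)
  storage.mode(x) <- "integer"
  x
}

#' Save an instance label mask
#'
#' Writes a label mask as a single-channel TIFF: 16-bit when the maximum
#' label fits in 65535, otherwise 32-bit unsigned integer. The round trip
#' `load_labels(save_labels(m))` is the pixelwise identity.
#'
#' @param mask Integer matrix, 0 = background.
#' @param path Output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
save_labels <- function(mask, path) {
  stopifnot(is.matrix(mask))
  if (any(mask < 0)) stop("labels must be non-negative")
  if (!(img_ext(path) %in% c("tif", "tiff")))
    stop("label masks are written as TIFF; use a .tif path")
  mx <- max(mask, 0L)
  if (mx <= 65535) {
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else {
    write_tiff_uint32(mask, path)
  }
  invisible(path)
}

# SampleFormat (tag 339) of the first IFD: 1 = unsigned int, 2 = signed
# int, 3 = float; 1 when the tag is absent. tiff::readTIFF rescales
# float samples onto the integer range under as.is, so float-typed masks
# must be caught before decoding.
tiff_sample_format <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- rawToChar(readBin(con, "raw", 2L))
  endian <- if (order_bytes == "II") "little" else "big"
  readBin(con, "integer", 1L, size = 2, endian = endian)  # magic 42
  ifd <- readBin(con, "integer", 1L, size = 4, endian = endian)
  seek(con, ifd)
  n <- readBin(con, "integer", 1L, size = 2, endian = endian)
  for (k in seq_len(n)) {
    tag <- readBin(con, "integer", 1L, size = 2, endian = endian,
                   signed = FALSE)
    readBin(con, "integer", 1L, size = 2, endian = endian)  # type
    readBin(con, "integer", 1L, size = 4, endian = endian)  # count
    value <- readBin(con, "integer", 1L, size = 2, endian = endian)
    readBin(con, "integer", 1L, size = 2, endian = endian)
    if (identical(tag, 339L)) return(value)
  }
  1L
}

# Minimal single-strip uncompressed 32-bit grayscale TIFF writer
# (little-endian), for the two sample formats tiff::writeTIFF cannot
# produce: unsigned 32-bit integers (big label masks; writeTIFF rescales
# everything onto [0,1]) and true 32-bit floats with SampleFormat = 3
# (writeTIFF's "32-bit" output is scaled unsigned integers).
# tiff::readTIFF reads both back exactly.
write_tiff32 <- function(x, path, format = c("uint", "float")) {
  format <- match.arg(format)
  h <- nrow(x); w <- ncol(x)
  con <- file(path, "wb")
  on.exit(close(con))
  data_offset <- 8L
  nbytes <- 4L * h * w
  ifd_offset <- data_offset + nbytes
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  # pixel data, row-major as TIFF expects
  if (format == "uint")
    writeBin(as.integer(t(x)), con, size = 4, endian = "little")
  else
    writeBin(as.numeric(t(x)), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT: value left-justified in 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  tags <- list(
    c(256L, 4L, 1L, w),            # ImageWidth
    c(257L, 4L, 1L, h),            # ImageLength
    c(258L, 3L, 1L, 32L),          # BitsPerSample
    c(259L, 3L, 1L, 1L),           # Compression = none
    c(262L, 3L, 1L, 1L),           # Photometric = BlackIsZero
    c(273L, 4L, 1L, data_offset),  # StripOffsets
    c(277L, 3L, 1L, 1L),           # SamplesPerPixel
    c(278L, 4L, 1L, h),            # RowsPerStrip
    c(279L, 4L, 1L, nbytes),       # StripByteCounts
    c(339L, 3L, 1L, if (format == "uint") 1L else 3L)  # SampleFormat
  )
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) entry(tg[1], tg[2], tg[3], tg[4])
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

write_tiff_uint32 <- function(mask, path) write_tiff32(mask, path, "uint")
write_tiff_float32 <- function(x, path) write_tiff32(x, path, "float")

#' Save a grayscale image or real-valued map
#'
#' Writes a numeric matrix as single-channel TIFF. Values in `[0, 1]`
#' (e.g. distance maps, synthetic renderings) are stored as 32-bit float;
#' integer-valued matrices are stored as 16-bit.
#'
#' @param img Numeric matrix.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(is.matrix(img))
  if (!(img_ext(path) %in% c("tif", "tiff")))
    stop("images are written as TIFF; use a .tif path")
  rng <- range(img)
  if (rng[1] >= 0 && rng[2] <= 1) {
    write_tiff_float32(img, path)
  } else if (all(img == round(img)) && rng[1] >= 0 && rng[2] <= 65535) {
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else {
    stop("cannot represent image range [", rng[1], ", ", rng[2],
         "] as TIFF; rescale first")
  }
  invisible(path)
}
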