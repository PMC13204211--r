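#' Calibrated image container
#'
#' A 2D intensity raster together with its physical calibration and the
#' per-image metadata carried through the pipeline (case, study group,
#' tissue compartment). Pixel values are either 8-bit intensities (0-255)
#' or a binary 0/1 mask. Coordinates throughout the package are
#' `(row, col)`, 1-based, origin at the top-left corner.
#'
#' @param pixels numeric or integer matrix.
#' @param microns_per_px physical side length of one pixel, in micrometers.
#' @param case_id,group,compartment optional metadata labels; `group` is
#'   conventionally one of `"control"`, `"short-term"`, `"long-term"` and
#'   `compartment` one of `"GM"`, `"WM"`, but any label is accepted.
#' @return an object of class `calibrated_image`.
#' @examples
#' img <- calibrated_image(matrix(0, 32, 32), microns_per_px = 0.25)
#' dim(img$pixels)
#' @export
calibrated_image <- function(pixels, microns_per_px,
                             case_id = NA_character_,
                             group = NA_character_,
                             compartment = NA_character_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!is.numeric(microns_per_px) || length(microns_per_px) != 1L ||
      !is.finite(microns_per_px) || microns_per_px <= 0)
    stop("microns_per_px must be a single positive number")
  structure(
    list(pixels = pixels,
         microns_per_px = microns_per_px,
         case_id = as.character(case_id),
         group = as.character(group),
         compartment = as.character(compartment)),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px", nrow(x$pixels),
              ncol(x$pixels), x$microns_per_px))
  if (!is.na(x$case_id)) cat(sprintf(", case %s", x$case_id))
  if (!is.na(x$group)) cat(sprintf(" [%s/%s]", x$group, x$compartment))
  cat("\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Minimal baseline TIFF: single-channel, 8-bit, uncompressed, one strip.
# No TIFF/PNG reader package is assumed; this covers exactly the files the
# package itself writes plus plain grayscale exports from common tools.
# ---------------------------------------------------------------------------

#' Write a grayscale image as an 8-bit uncompressed TIFF
#'
#' @param image a `calibrated_image` or a numeric matrix; values are clamped
#'   to 0-255 and rounded. Binary 0/1 masks are scaled to 0/255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_gray <- function(image, path) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  stopifnot(is.matrix(px))
  if (max(px) <= 1 && min(px) >= 0 && all(px == round(px))) px <- px * 255
  px <- pmin(pmax(round(px), 0), 255)
  h <- nrow(px); w <- ncol(px)
  # pixel data row-major (TIFF scanlines)
  data <- as.integer(t(px))
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  wr2(42L)
  data_off <- 8L
  ifd_off <- data_off + length(data)
  wr4(ifd_off)
  writeBin(as.raw(data), con)
  tags <- list(
    c(256L, 3L, 1L, w),        # ImageWidth
    c(257L, 3L, 1L, h),        # ImageLength
    c(258L, 3L, 1L, 8L),       # BitsPerSample
    c(259L, 3L, 1L, 1L),       # Compression = none
    c(262L, 3L, 1L, 1L),       # Photometric = BlackIsZero
    c(273L, 4L, 1L, data_off), # StripOffsets
    c(277L, 3L, 1L, 1L),       # SamplesPerPixel
    c(278L, 3L, 1L, h),        # RowsPerStrip
    c(279L, 4L, 1L, length(data))  # StripByteCounts
  )
  wr2(length(tags))
  for (tg in tags) {
    wr2(tg[1]); wr2(tg[2]); wr4(tg[3])
    if (tg[2] == 3L) { wr2(tg[4]); wr2(0L) } else wr4(tg[4])
  }
  wr4(0L)  # next IFD
  invisible(path)
}

#' Read an 8-bit grayscale uncompressed TIFF
#'
#' Supports the baseline subset written by [write_tiff_gray()] (little- or
#' big-endian, one or more strips, no compression, one 8-bit sample).
#'
#' @param path file path.
#' @param microns_per_px calibration to attach (TIFF resolution tags are not
#'   interpreted).
#' @param ... further metadata passed to [calibrated_image()].
#' @return a `calibrated_image`.
#' @export
read_tiff_gray <- function(path, microns_per_px, ...) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stop("not a TIFF file: ", path)
  rd <- function(off, size, n = 1L)  # unsigned only supported below 4 bytes
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size >= 4L)
  if (rd(2, 2) != 42L) stop("not a TIFF file: ", path)
  ifd <- rd(4, 4)
  nent <- rd(ifd, 2)
  tags <- list()
  for (i in seq_len(nent)) {
    e <- ifd + 2 + (i - 1) * 12
    id <- rd(e, 2); typ <- rd(e + 2, 2); cnt <- rd(e + 4, 4)
    size <- c(1L, 1L, 2L, 4L)[match(typ, c(1L, 2L, 3L, 4L))]
    if (is.na(size)) next
    vals <- if (size * cnt <= 4) rd(e + 8, size, cnt) else rd(rd(e + 8, 4), size, cnt)
    tags[[as.character(id)]] <- vals
  }
  need <- function(id) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) stop("TIFF tag ", id, " missing in ", path)
    v
  }
  w <- need(256); h <- need(257)
  if (!identical(tags[["259"]], 1L) && !is.null(tags[["259"]]))
    stop("compressed TIFF not supported: ", path)
  if (!is.null(tags[["258"]]) && any(tags[["258"]] != 8L))
    stop("only 8-bit grayscale TIFF supported: ", path)
  offs <- need(273); cnts <- need(279)
  bytes <- integer(0)
  for (i in seq_along(offs))
    bytes <- c(bytes, rd(offs[i], 1, cnts[i]))
  if (length(bytes) != w * h) stop("TIFF pixel data size mismatch: ", path)
  px <- matrix(bytes, nrow = h, ncol = w, byrow = TRUE)
  calibrated_image(px, microns_per_px = microns_per_px, ...)
}

#' Write a binary or grayscale mask as a PGM (P5) file
#'
#' @param mask logical or numeric matrix; logical masks are written 0/255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(mask, path) {
  px <- if (is.logical(mask)) ifelse(mask, 255L, 0L) else
    pmin(pmax(round(mask), 0), 255)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(px), nrow(px)), con, eos = NULL)
  writeBin(as.raw(as.integer(t(px))), con)
  invisible(path)
}

#' Read an image by file extension
#'
#' Dispatches on extension: `.tif`/`.tiff` via [read_tiff_gray()], `.pgm`
#' (binary P5) via a built-in reader.
#'
#' @inheritParams read_tiff_gray
#' @return a `calibrated_image`.
#' @export
read_image <- function(path, microns_per_px, ...) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    return(read_tiff_gray(path, microns_per_px, ...))
  if (ext == "pgm") {
    raw <- readBin(path, "raw", n = file.size(path))
    if (length(raw) < 4 || rawToChar(raw[1:2]) != "P5")
      stop("only P5 PGM supported: ", path)
    # parse the 3 whitespace-delimited header tokens byte-wise (the pixel
    # data that follows is binary and may contain any byte value)
    ws <- as.raw(c(32, 9, 10, 13))
    i <- 3L
    tokens <- integer(0)
    while (length(tokens) < 3 && i <= length(raw)) {
      while (i <= length(raw) && raw[i] %in% ws) i <- i + 1L
      j <- i
      while (j <= length(raw) && !(raw[j] %in% ws)) j <- j + 1L
      tokens <- c(tokens, as.integer(rawToChar(raw[i:(j - 1)])))
      i <- j
    }
    i <- i + 1L  # single whitespace after maxval
    w <- tokens[1]; h <- tokens[2]
    data <- raw[i:(i + w * h - 1)]
    px <- matrix(as.integer(data), nrow = h, ncol = w, byrow = TRUE)
    return(calibrated_image(px, microns_per_px = microns_per_px, ...))
  }
  stop("unsupported image format: ", path)
}
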