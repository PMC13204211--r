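## Binary raster utilities shared across modules. All masks are logical
## matrices; connectivity defaults to 8 to match the skeleton stage.

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of labels (0 = background, 1..k = components).
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  cpp_label_components(mask_to_int(mask), as.integer(connectivity))
}

mask_to_int <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  m[is.na(m)] <- 0L
  m
}

#' Euclidean distance transform
#'
#' Distance from every pixel to the nearest `FALSE` pixel of `mask`
#' (exact Euclidean metric). Pixels of an all-`TRUE` mask get `Inf`.
#'
#' @param mask logical matrix.
#' @return numeric matrix of distances in pixels.
#' @export
distance_transform <- function(mask) {
  d <- cpp_edt(mask_to_int(mask))
  d[d > 1e5] <- Inf  # sentinel: no background pixel in the image
  d
}

#' Morphological erosion/dilation/opening with a Euclidean disc
#'
#' Implemented through the exact distance transform, so the structuring
#' element is a true Euclidean disc of the given radius.
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels (`>= 0`; 0 is the identity).
#' @return logical matrix.
#' @export
binary_erode <- function(mask, radius) {
  if (radius <= 0) return(mask != 0)
  distance_transform(mask) > radius
}

#' @rdname binary_erode
#' @export
binary_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask != 0)
  if (!any(mask)) return(mask != 0)
  cpp_edt(mask_to_int(!mask)) <= radius
}

#' @rdname binary_erode
#' @export
binary_open <- function(mask, radius) {
  binary_dilate(binary_erode(mask, radius), radius)
}

#' Otsu's threshold for an 8-bit image
#'
#' Maximizes between-class variance over the 256-bin histogram. Returns
#' `NA` when the image is constant (no threshold separates anything).
#'
#' @param pixels numeric matrix with values in 0-255.
#' @return threshold value `t`; foreground is `pixels > t`. `NA` if constant.
#' @export
otsu_threshold <- function(pixels) {
  v <- as.integer(pmin(pmax(round(pixels), 0), 255))
  if (length(unique(v)) < 2L) return(NA_real_)
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -1
  which.max(sigma_b) - 1  # threshold t: fg = value > t
}

#' Rasterize a line segment (Bresenham)
#'
#' @param r0,c0,r1,c1 endpoints, 1-based (row, col).
#' @return two-column integer matrix of (row, col) pixels, endpoint to
#'   endpoint inclusive; 8-connected.
#' @export
bresenham_line <- function(r0, c0, r1, c1) {
  r0 <- round(r0); c0 <- round(c0); r1 <- round(r1); c1 <- round(c1)
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2)
  err <- dr - dc
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2 * err
    if (e2 > -dc) { err <- err - dc; r <- r + sr }
    if (e2 < dr) { err <- err + dr; c <- c + sc }
  }
  out
}

#' Pixels of a filled disc
#'
#' @param center (row, col) center.
#' @param radius disc radius in pixels.
#' @param shape (nrow, ncol) of the target grid; pixels outside are dropped.
#' @return two-column integer matrix of (row, col) pixels with
#'   `dist(center) <= radius`.
#' @export
disc_pixels <- function(center, radius, shape) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(shape[1], ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(shape[2], ceiling(center[2] + radius))
  if (r0 > r1 || c0 > c1) return(matrix(integer(0), 0, 2))
  gr <- r0:r1; gc <- c0:c1
  dd <- outer((gr - center[1])^2, (gc - center[2])^2, `+`)
  idx <- which(dd <= radius^2, arr.ind = TRUE)
  cbind(gr[idx[, 1]], gc[idx[, 2]])
}

set_pixels <- function(mat, px, value) {
  if (nrow(px)) mat[cbind(px[, 1], px[, 2])] <- value
  mat
}

## Area (pixel count) of each label in a label matrix, as a named vector.
component_areas <- function(labels) {
  k <- max(labels)
  if (k == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = k)
}
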