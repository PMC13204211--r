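## Skeletonization of the process mask and concentric-ring Sholl profiling.
## Rings are digitized with the grid-intersection (supercover) rule: every
## pixel whose unit square the true circle passes through is included. The
## resulting digital ring is a closed 4-connected curve, so an 8-connected
## skeleton can never cross it without sharing a pixel (digital Jordan
## property) -- the guarantee that makes run-mode counting sound.

#' Skeletonize a process mask and classify its pixels
#'
#' Thins the mask to a 1-px-wide, topology-preserving skeleton
#' (Zhang-Suen), optionally prunes short terminal spurs created by
#' thinning thick limbs, and classifies pixels against the soma mask:
#' endpoints (exactly one skeleton 8-neighbor), branch points (three or
#' more), and primary attachments (skeleton pixels 8-adjacent to the
#' soma).
#'
#' @param process_mask logical matrix (soma already removed); an empty
#'   mask yields an empty skeleton.
#' @param soma_mask logical matrix used for attachment classification
#'   (optional; no attachments are reported without it).
#' @param prune_px prune terminal spurs strictly shorter than this many
#'   pixels (default 4; 0 disables). Whole components are never removed.
#' @return an object of class `skeleton`: list with `mask` (logical),
#'   `endpoints`, `branch_points`, `attachments` (two-column coordinate
#'   matrices), and `soma_mask`.
#' @export
skeletonize_processes <- function(process_mask, soma_mask = NULL,
                                  prune_px = 4L) {
  process_mask <- process_mask != 0
  sk <- cpp_thin_zhang_suen(mask_to_int(process_mask)) > 0
  if (prune_px > 0 && any(sk)) sk <- prune_spurs(sk, prune_px)
  classify_skeleton(sk, soma_mask)
}

## Remove terminal spurs shorter than min_len px, but never an entire
## component (an unbranched arm is not a spur).
prune_spurs <- function(sk, min_len) {
  repeat {
    nb <- cpp_neighbor_count8(mask_to_int(sk))
    eps <- which(nb == 1L, arr.ind = TRUE)
    if (!nrow(eps)) return(sk)
    removed_any <- FALSE
    for (k in seq_len(nrow(eps))) {
      if (!sk[eps[k, 1], eps[k, 2]]) next
      path <- walk_skeleton(sk, eps[k, ], min_len + 1L)
      if (nrow(path) > min_len) next            # long branch, keep
      # the walk stopped at a branch point (or ran out): a spur only if the
      # far end has >= 3 neighbors once the spur is gone
      last <- path[nrow(path), ]
      nb_last <- cpp_neighbor_count8(mask_to_int(sk))[last[1], last[2]]
      if (nb_last < 3) next                     # isolated short arm, keep
      drop <- path[-nrow(path), , drop = FALSE]
      sk <- set_pixels(sk, drop, FALSE)
      removed_any <- TRUE
    }
    if (!removed_any) return(sk)
  }
}

## Attachment tolerance: thinning a blunt process stub retracts its proximal
## end by up to ~3 px from the soma boundary, so "adjacent to the soma" is
## operationalized as within this distance of the soma mask.
SOMA_ATTACH_DIST <- 3.5

classify_skeleton <- function(sk, soma_mask = NULL) {
  nb <- cpp_neighbor_count8(mask_to_int(sk))
  eps <- which(nb == 1L, arr.ind = TRUE)
  bps <- which(nb >= 3L, arr.ind = TRUE)
  atts <- matrix(integer(0), 0, 2)
  if (!is.null(soma_mask) && any(soma_mask) && any(sk)) {
    near_soma <- binary_dilate(soma_mask != 0, SOMA_ATTACH_DIST)
    atts <- which(sk & near_soma & !(soma_mask != 0), arr.ind = TRUE)
  }
  structure(list(mask = sk, endpoints = eps, branch_points = bps,
                 attachments = atts, soma_mask = soma_mask),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d px, %d endpoints, %d branch points, %d soma-attachment px\n",
              sum(x$mask), nrow(x$endpoints), nrow(x$branch_points),
              nrow(x$attachments)))
  invisible(x)
}

#' Rasterize one concentric Sholl ring
#'
#' Grid-intersection (supercover) digitization of the circle of the given
#' radius: a pixel belongs to the ring when the true circle intersects its
#' unit square. The ring is a closed 4-connected digital curve (8 pixels
#' at radius 1), clipped to the grid near borders.
#'
#' @param center (row, col) circle center.
#' @param radius circle radius in px (`> 0`).
#' @param shape (nrow, ncol) of the grid.
#' @return logical matrix with ring pixels `TRUE`.
#' @export
rasterize_ring <- function(center, radius, shape) {
  stopifnot(radius > 0)
  r0 <- max(1L, floor(center[1] - radius - 1)); r1 <- min(shape[1], ceiling(center[1] + radius + 1))
  c0 <- max(1L, floor(center[2] - radius - 1)); c1 <- min(shape[2], ceiling(center[2] + radius + 1))
  out <- matrix(FALSE, shape[1], shape[2])
  if (r0 > r1 || c0 > c1) return(out)
  gr <- r0:r1; gc <- c0:c1
  adr <- abs(gr - center[1]); adc <- abs(gc - center[2])
  # nearest / farthest point of each unit pixel square from the center
  dmin <- sqrt(outer(pmax(adr - 0.5, 0)^2, pmax(adc - 0.5, 0)^2, `+`))
  dmax <- sqrt(outer((adr + 0.5)^2, (adc + 0.5)^2, `+`))
  sel <- dmin <= radius & radius <= dmax
  idx <- which(sel, arr.ind = TRUE)
  out[cbind(gr[idx[, 1]], gc[idx[, 2]])] <- TRUE
  out
}

#' Compute a concentric-ring Sholl profile of a skeleton
#'
#' Rings are centered on the soma center and spaced at a constant radial
#' increment (10 px in the published workflow). Two counting modes are
#' provided: `"pixel"` counts skeleton pixels lying on each ring (the
#' pixel-level-crossing definition behind the published intersection
#' totals, and the default), `"run"` counts 8-connected runs of
#' skeleton-on-ring pixels (the classical crossing count). Run counts
#' never exceed pixel counts.
#'
#' @param skeleton a `skeleton` object or a logical matrix.
#' @param center (row, col) soma center.
#' @param interval ring spacing in px (`>= 1`, default 10).
#' @param mode `"pixel"` or `"run"`.
#' @return an object of class `sholl_profile`: list with `center`,
#'   `interval`, `mode`, `radii` (px, multiples of `interval` up to the
#'   largest ring intersecting the grid), `counts`, and
#'   `last_intersection_radius` (px; 0 if all counts are zero).
#' @export
sholl_profile <- function(skeleton, center, interval = 10, mode = c("pixel", "run")) {
  mode <- match.arg(mode)
  stopifnot(interval >= 1)
  sk <- if (inherits(skeleton, "skeleton")) skeleton$mask else skeleton != 0
  shape <- dim(sk)
  corners <- rbind(c(1, 1), c(1, shape[2]), c(shape[1], 1), shape)
  dmax <- sqrt(max((corners[, 1] - center[1])^2 + (corners[, 2] - center[2])^2))
  radii <- seq(interval, by = interval,
               length.out = max(1L, floor(dmax / interval)))
  counts <- integer(length(radii))
  if (any(sk)) {
    # distance of every skeleton pixel from the center; a pixel can sit on
    # ring r only when |dist - r| <= sqrt(2)/2 + 0.5, so each ring tests a
    # narrow annulus of candidates
    skpx <- which(sk, arr.ind = TRUE)
    dist <- sqrt((skpx[, 1] - center[1])^2 + (skpx[, 2] - center[2])^2)
    for (i in seq_along(radii)) {
      r <- radii[i]
      cand <- which(abs(dist - r) <= 1.21)
      if (!length(cand)) next
      on_ring <- ring_membership(skpx[cand, , drop = FALSE], center, r)
      if (!any(on_ring)) next
      if (mode == "pixel") {
        counts[i] <- sum(on_ring)
      } else {
        pts <- skpx[cand[on_ring], , drop = FALSE]
        counts[i] <- count_crossing_clusters(pts)
      }
    }
  }
  lir <- if (any(counts > 0)) max(radii[counts > 0]) else 0
  structure(list(center = center, interval = interval, mode = mode,
                 radii = radii, counts = counts,
                 last_intersection_radius = lir),
            class = "sholl_profile")
}

## supercover membership test for a set of pixel coordinates
ring_membership <- function(px, center, radius) {
  adr <- abs(px[, 1] - center[1]); adc <- abs(px[, 2] - center[2])
  dmin <- sqrt(pmax(adr - 0.5, 0)^2 + pmax(adc - 0.5, 0)^2)
  dmax <- sqrt((adr + 0.5)^2 + (adc + 0.5)^2)
  dmin <= radius & radius <= dmax
}

## Crossing clusters for run-mode counting: one crossing of a digital curve
## over a digital ring can leave on-ring pixels separated by a 2-px
## Chebyshev gap (the curve dips between diagonal ring pixels), so pixels
## within Chebyshev distance 2 are merged into one crossing.
count_crossing_clusters <- function(pts) {
  n <- nrow(pts)
  if (n == 0) return(0L)
  if (n == 1) return(1L)
  r0 <- min(pts[, 1]) - 2L; c0 <- min(pts[, 2]) - 2L
  m <- matrix(FALSE, max(pts[, 1]) - r0 + 3L, max(pts[, 2]) - c0 + 3L)
  m[cbind(pts[, 1] - r0, pts[, 2] - c0)] <- TRUE
  md <- cpp_max_filter(matrix(as.numeric(m), nrow(m), ncol(m)), 1L) > 0
  max(label_components(md, 8L))
}

## number of 8-connected components of a small point set
count_point_components8 <- function(pts) {
  n <- nrow(pts)
  if (n == 0) return(0L)
  if (n == 1) return(1L)
  r0 <- min(pts[, 1]) - 1L; c0 <- min(pts[, 2]) - 1L
  m <- matrix(FALSE, max(pts[, 1]) - r0 + 1L, max(pts[, 2]) - c0 + 1L)
  m[cbind(pts[, 1] - r0, pts[, 2] - c0)] <- TRUE
  max(label_components(m, 8L))
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat(sprintf("<sholl_profile> %s mode, interval %g px, %d rings, total %d, last intersection at %g px\n",
              x$mode, x$interval, length(x$radii), sum(x$counts),
              x$last_intersection_radius))
  invisible(x)
}

#' Last Sholl intersection radius in micrometers
#'
#' @param profile a [sholl_profile()].
#' @param microns_per_px calibration (`> 0`).
#' @return radius of the most distal intersecting ring, in um (0 when the
#'   profile has no intersections).
#' @export
last_intersection_radius_um <- function(profile, microns_per_px) {
  stopifnot(inherits(profile, "sholl_profile"), microns_per_px > 0)
  profile$last_intersection_radius * microns_per_px
}

#' Serialize a Sholl profile to CSV (+ JSON header)
#'
#' Writes `radius_px, radius_um, count` rows and a sidecar JSON recording
#' center, interval, mode and calibration.
#'
#' @param profile a [sholl_profile()].
#' @param path CSV output path; header JSON goes to `<path>.json`.
#' @param microns_per_px calibration used for the `radius_um` column.
#' @return `path`, invisibly.
#' @export
write_sholl_profile <- function(profile, path, microns_per_px) {
  df <- data.frame(radius_px = profile$radii,
                   radius_um = profile$radii * microns_per_px,
                   count = profile$counts)
  write.csv(df, path, row.names = FALSE)
  hdr <- list(center_row = profile$center[1], center_col = profile$center[2],
              interval_px = profile$interval, mode = profile$mode,
              microns_per_px = microns_per_px,
              coordinate_convention = "(row, col), 1-based, origin top-left")
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
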