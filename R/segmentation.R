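## Segmentation of single-cell ROIs and counting fields: thresholding,
## optional watershed separation of touching objects, constrained gap
## closing of interrupted processes, and automated soma/process separation.

#' Segment the cell in a calibrated single-cell image
#'
#' Thresholds the image (Otsu by default, or a fixed value), optionally
#' splits touching objects with a distance-transform watershed, and keeps
#' the connected component containing the image center (or, if the center
#' is background, the component nearest to it).
#'
#' @param image a [calibrated_image()].
#' @param threshold `"otsu"` or a numeric threshold; foreground is
#'   `pixels > threshold`.
#' @param use_watershed split touching objects before selecting the center
#'   component.
#' @return logical cell mask.
#' @export
segment_cell <- function(image, threshold = "otsu", use_watershed = FALSE) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  thr <- if (identical(threshold, "otsu")) otsu_threshold(px) else
    as.numeric(threshold)
  if (is.na(thr)) stop("no signal: image is constant, cannot threshold")
  mask <- px > thr
  if (!any(mask)) stop("no signal: empty foreground after thresholding")
  if (use_watershed) mask <- watershed_split(mask)
  keep_center_component(mask)
}

## Keep the 8-connected component containing (or nearest to) the center.
keep_center_component <- function(mask) {
  lab <- label_components(mask, 8L)
  ctr <- round(c((nrow(mask) + 1) / 2, (ncol(mask) + 1) / 2))
  l <- lab[ctr[1], ctr[2]]
  if (l == 0L) {
    fg <- which(lab > 0L, arr.ind = TRUE)
    d2 <- (fg[, 1] - ctr[1])^2 + (fg[, 2] - ctr[2])^2
    l <- lab[fg[which.min(d2), , drop = FALSE]]
  }
  lab == l
}

#' Split touching objects with a distance-transform watershed
#'
#' Markers are the plateau regions of the distance transform that are
#' within 0.5 px of the local maximum in a square window; basins are
#' flooded from high to low distance, and pixels where two basins meet are
#' removed so that connected-component labeling separates the objects.
#'
#' @param mask logical matrix.
#' @param marker_window half-width (px) of the local-maximum window used to
#'   seed basins; larger values merge nearby peaks (fewer splits).
#' @return logical matrix with watershed lines removed.
#' @export
watershed_split <- function(mask, marker_window = 5L) {
  if (!any(mask)) return(mask)
  d <- distance_transform(mask)
  mm <- cpp_max_filter(d, as.integer(marker_window))
  markers <- mask & (d >= mm - 0.5)
  mlab <- label_components(markers, 8L)
  lab <- cpp_watershed_flood(mask_to_int(mask), mlab, d)
  if (max(lab) <= 1L) return(mask)
  boundary <- boundary_between_labels(lab)
  mask & !boundary
}

## Pixels whose 8-neighborhood contains a different positive label.
boundary_between_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  out <- matrix(FALSE, nr, nc)
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (s in shifts) {
    sh <- matrix(0L, nr, nc)
    rs <- max(1, 1 + s[1]):min(nr, nr + s[1])
    cs <- max(1, 1 + s[2]):min(nc, nc + s[2])
    sh[rs - s[1], cs - s[2]] <- lab[rs, cs]
    out <- out | (lab > 0L & sh > 0L & sh != lab)
  }
  out
}

#' Close sectioning-related gaps between process fragments
#'
#' Bridges pairs of fragment endpoints that are within `max_gap` pixels of
#' each other and whose local orientations are near-collinear with the
#' bridge, by drawing a 1-px segment between them. No other pixels are ever
#' added, so no branch is created de novo; `max_gap = 0` is the identity.
#' The operation never removes foreground and never increases the number
#' of connected components.
#'
#' @param mask logical process mask.
#' @param max_gap maximum endpoint-to-endpoint bridge length, px.
#' @param max_angle maximum deviation (degrees) between each endpoint's
#'   outgoing direction and the bridge direction.
#' @return logical matrix.
#' @export
close_gaps <- function(mask, max_gap, max_angle = 50) {
  stopifnot(max_gap >= 0)
  if (max_gap == 0 || !any(mask)) return(mask != 0)
  lab <- label_components(mask, 8L)
  skel <- cpp_thin_zhang_suen(mask_to_int(mask)) > 0
  eps <- endpoint_directions(skel)
  if (nrow(eps$coords) < 2) return(mask != 0)
  comp <- lab[eps$coords]
  n <- nrow(eps$coords)
  # thinning retracts blunt fragment ends by a few pixels, so the true tip
  # of a fragment is the mask pixel of its component nearest to the other
  # fragment; skeleton endpoints provide the candidate pairs and the local
  # orientation only
  retract <- 5
  tip_px <- lapply(seq_len(n), function(i) {
    e <- eps$coords[i, ]
    r0 <- max(1, e[1] - retract); r1 <- min(nrow(mask), e[1] + retract)
    c0 <- max(1, e[2] - retract); c1 <- min(ncol(mask), e[2] + retract)
    loc <- which(lab[r0:r1, c0:c1] == comp[i], arr.ind = TRUE)
    cbind(loc[, 1] + r0 - 1, loc[, 2] + c0 - 1)
  })
  cand <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (comp[i] == comp[j]) next
    b <- eps$coords[j, ] - eps$coords[i, ]
    dist_e <- sqrt(sum(b^2))
    if (dist_e > max_gap + 2 * retract || dist_e == 0) next
    bu <- b / dist_e
    a1 <- angle_between(eps$dirs[i, ], bu)
    a2 <- angle_between(eps$dirs[j, ], -bu)
    if (a1 > max_angle || a2 > max_angle) next
    # closest pair of mask pixels between the two fragments
    pi_ <- tip_px[[i]]; pj <- tip_px[[j]]
    dd <- outer(pi_[, 1], pj[, 1], `-`)^2 + outer(pi_[, 2], pj[, 2], `-`)^2
    best <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    gap <- sqrt(dd[best[1], best[2]])
    if (gap > max_gap) next
    cand <- rbind(cand, c(comp[i], comp[j], gap,
                          pi_[best[1], ], pj[best[2], ]))
  }
  if (is.null(cand)) return(mask != 0)
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  out <- mask != 0
  root <- seq_len(max(lab))
  find <- function(x) { while (root[x] != x) x <- root[x]; x }
  for (k in seq_len(nrow(cand))) {
    ri <- find(cand[k, 1]); rj <- find(cand[k, 2])
    if (ri == rj) next
    px <- bresenham_line(cand[k, 4], cand[k, 5], cand[k, 6], cand[k, 7])
    out <- set_pixels(out, px, TRUE)
    root[ri] <- rj
  }
  out
}

## Skeleton endpoints with outgoing unit directions estimated from up to
## `steps` pixels back along the skeleton curve.
endpoint_directions <- function(skel, steps = 5L) {
  nb <- cpp_neighbor_count8(mask_to_int(skel))
  ep <- which(nb == 1L, arr.ind = TRUE)
  dirs <- matrix(0, nrow(ep), 2)
  for (k in seq_len(nrow(ep))) {
    path <- walk_skeleton(skel, ep[k, ], steps)
    back <- path[nrow(path), ]
    v <- ep[k, ] - back
    nv <- sqrt(sum(v^2))
    dirs[k, ] <- if (nv > 0) v / nv else c(0, 0)
  }
  list(coords = ep, dirs = dirs)
}

## Walk from an endpoint along the skeleton for up to `steps` moves,
## stopping at a branch point; returns visited coordinates.
walk_skeleton <- function(skel, start, steps) {
  path <- matrix(start, 1, 2)
  cur <- start
  prev <- c(NA, NA)
  for (s in seq_len(steps)) {
    nb <- neighbors8(cur, dim(skel))
    nb <- nb[skel[nb], , drop = FALSE]
    if (nrow(path) > 1)
      nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
    on_path <- apply(nb, 1, function(p)
      any(path[, 1] == p[1] & path[, 2] == p[2]))
    nb <- nb[!on_path, , drop = FALSE]
    if (nrow(nb) != 1) break
    prev <- cur
    cur <- nb[1, ]
    path <- rbind(path, cur)
  }
  path
}

neighbors8 <- function(p, shape) {
  off <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  nb <- cbind(p[1] + off[, 1], p[2] + off[, 2])
  nb[nb[, 1] >= 1 & nb[, 1] <= shape[1] &
       nb[, 2] >= 1 & nb[, 2] <= shape[2], , drop = FALSE]
}

angle_between <- function(u, v) {
  d <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(pmin(pmax(d, -1), 1)) * 180 / pi
}

#' Separate the soma from the processes of a segmented cell
#'
#' The soma is the connected core that survives morphological opening with
#' the largest Euclidean-disc radius whose opening still covers the soma
#' seed point (the supplied hint, or the center of the mask's maximal
#' inscribed disc). If opening degenerates (core radius < 2 px, e.g. a
#' hint placed inside a thin process), the maximal inscribed disc is used
#' as the soma instead.
#'
#' @param cell_mask logical mask of one cell.
#' @param soma_center_hint optional (row, col) seed; must be a foreground
#'   pixel.
#' @param boundary_slack extra dilation (px) applied to the opened core,
#'   clipped to the cell mask. A rasterized (especially nearest-neighbor
#'   upscaled) soma boundary is a staircase that a pure Euclidean opening
#'   clips; one pixel of slack per upscale factor restores it, keeping
#'   soma area consistent across ROI scale factors. Pass the ROI scale
#'   factor (1 for native-resolution images).
#' @return an object of class `segmentation_result`: list with `cell_mask`,
#'   `soma_mask`, `process_mask` (= cell minus soma), `soma_center`
#'   (centroid of the soma, snapped to a soma pixel), and the opening
#'   radius used (`soma_open_radius`, `NA` if the disc fallback fired).
#' @export
separate_soma <- function(cell_mask, soma_center_hint = NULL,
                          boundary_slack = 1) {
  cell_mask <- cell_mask != 0
  if (!any(cell_mask)) stop("empty cell mask")
  d <- distance_transform(cell_mask)
  d[!cell_mask] <- 0
  if (is.null(soma_center_hint)) {
    soma_center_hint <- which(d == max(d), arr.ind = TRUE)[1, ]
  } else {
    soma_center_hint <- round(soma_center_hint)
    if (!cell_mask[soma_center_hint[1], soma_center_hint[2]])
      stop("soma_center_hint is not a foreground pixel")
  }
  rmax <- ceiling(max(d))
  soma <- NULL
  r_used <- NA_real_
  for (r in rev(seq_len(rmax))) {
    if (r < 2) break
    core <- binary_erode(cell_mask, r)
    opened <- binary_dilate(core, r) & cell_mask
    if (opened[soma_center_hint[1], soma_center_hint[2]]) {
      soma_full <- binary_dilate(core, r + boundary_slack) & cell_mask
      lab <- label_components(soma_full, 8L)
      soma <- lab == lab[soma_center_hint[1], soma_center_hint[2]]
      r_used <- r
      break
    }
  }
  if (is.null(soma)) {
    # fallback: maximal inscribed disc as the soma
    ctr <- which(d == max(d), arr.ind = TRUE)[1, ]
    rad <- max(d)
    if (rad < 1) stop("cell has no resolvable soma core")
    soma <- matrix(FALSE, nrow(cell_mask), ncol(cell_mask))
    soma <- set_pixels(soma, disc_pixels(ctr, rad, dim(cell_mask)), TRUE)
    soma <- soma & cell_mask
    if (!any(soma)) stop("cell has no resolvable soma core")
  }
  ctr <- round(c(mean(which(soma, arr.ind = TRUE)[, 1]),
                 mean(which(soma, arr.ind = TRUE)[, 2])))
  if (!soma[ctr[1], ctr[2]]) {
    sp <- which(soma, arr.ind = TRUE)
    ctr <- sp[which.min((sp[, 1] - ctr[1])^2 + (sp[, 2] - ctr[2])^2), ]
  }
  structure(list(cell_mask = cell_mask,
                 soma_mask = soma,
                 process_mask = cell_mask & !soma,
                 soma_center = as.integer(ctr),
                 soma_open_radius = r_used),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> cell %d px, soma %d px (center %d,%d), processes %d px\n",
              sum(x$cell_mask), sum(x$soma_mask), x$soma_center[1],
              x$soma_center[2], sum(x$process_mask)))
  invisible(x)
}

#' Count immunopositive cells in a field image
#'
#' Thresholds the field and counts connected foreground components whose
#' physical area reaches `min_object_area`. A constant (signal-free) image
#' counts zero cells.
#'
#' @param image a [calibrated_image()].
#' @param min_object_area minimum object area in um^2 (default 20).
#' @param threshold `"otsu"` or a numeric threshold.
#' @return integer cell count.
#' @export
count_cells_in_field <- function(image, min_object_area = 20,
                                 threshold = "otsu") {
  stopifnot(inherits(image, "calibrated_image"))
  thr <- if (identical(threshold, "otsu")) otsu_threshold(image$pixels) else
    as.numeric(threshold)
  if (is.na(thr)) return(0L)
  mask <- image$pixels > thr
  if (!any(mask)) return(0L)
  lab <- label_components(mask, 8L)
  areas_um2 <- component_areas(lab) * image$microns_per_px^2
  sum(areas_um2 >= min_object_area)
}

#' Summarize per-field counts into a per-case record
#'
#' The per-case cumulative count (sum over the 10 counting fields, by the
#' published design) is the unit used for between-group statistics; the
#' per-field distribution is retained for per-field analyses.
#'
#' @param field_counts nonnegative integer vector (one entry per field).
#' @param case_id,group,compartment metadata labels.
#' @return an object of class `field_count_record`.
#' @examples
#' summarize_case(rep(3, 10))$cumulative  # 30
#' @export
summarize_case <- function(field_counts, case_id = NA_character_,
                           group = NA_character_,
                           compartment = NA_character_) {
  if (!length(field_counts)) stop("field_counts must be nonempty")
  if (any(field_counts < 0)) stop("negative field counts")
  structure(list(case_id = as.character(case_id),
                 group = as.character(group),
                 compartment = as.character(compartment),
                 field_counts = as.integer(field_counts),
                 cumulative = as.integer(sum(field_counts))),
            class = "field_count_record")
}

#' @export
as.data.frame.field_count_record <- function(x, ...) {
  fc <- as.list(x$field_counts)
  names(fc) <- paste0("field_", seq_along(fc))
  data.frame(case_id = x$case_id, group = x$group,
             compartment = x$compartment, fc, cumulative = x$cumulative,
             check.names = FALSE)
}
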