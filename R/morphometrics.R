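## The six per-cell morphometric descriptors, computed from a cell's
## segmentation, skeleton, and Sholl profile.

#' Soma size in square micrometers
#'
#' Foreground pixel count of the soma mask scaled by the squared
#' calibration.
#'
#' @param soma_mask logical matrix.
#' @param microns_per_px calibration (`> 0`).
#' @return area in um^2.
#' @export
soma_size <- function(soma_mask, microns_per_px) {
  stopifnot(microns_per_px > 0)
  n <- sum(soma_mask != 0)
  if (n == 0) stop("empty soma mask")
  if (n <= 4)
    warning("very small soma (", n, " px); check segmentation")
  n * microns_per_px^2
}

#' Maximum process length in micrometers
#'
#' Straight-line distance from the soma outline to the most distal process
#' reaching the last intersecting Sholl ring: among skeleton pixels lying
#' on that ring, the maximum Euclidean distance to the nearest
#' soma-boundary pixel. Quantized to the ring spacing by construction (no
#' interpolation beyond the last ring).
#'
#' @param skeleton a `skeleton` object.
#' @param soma_mask logical soma mask.
#' @param profile the [sholl_profile()] computed from this skeleton.
#' @param microns_per_px calibration (`> 0`).
#' @return length in um; 0 (with a warning) for an empty skeleton or a
#'   profile with no intersections.
#' @export
max_process_length <- function(skeleton, soma_mask, profile, microns_per_px) {
  stopifnot(inherits(profile, "sholl_profile"), microns_per_px > 0)
  sk <- skeleton$mask
  if (!any(sk) || profile$last_intersection_radius == 0) {
    warning("empty skeleton or no Sholl intersections; max process length 0")
    return(0)
  }
  ring <- rasterize_ring(profile$center, profile$last_intersection_radius,
                         dim(sk))
  pts <- which(sk & ring, arr.ind = TRUE)
  if (!nrow(pts)) {
    warning("no skeleton pixel on the last ring; max process length 0")
    return(0)
  }
  boundary <- soma_boundary(soma_mask)
  if (!any(boundary)) stop("empty soma mask")
  # distance of every pixel to the nearest soma-boundary pixel
  dist_to_boundary <- cpp_edt(mask_to_int(!boundary))
  max(dist_to_boundary[pts]) * microns_per_px
}

## soma pixels 4-adjacent to background (the outline)
soma_boundary <- function(soma_mask) {
  m <- soma_mask != 0
  eroded <- binary_erode(m, 1)
  m & !eroded
}

#' Total number of Sholl intersections
#'
#' Sum of the per-ring counts, a measure of arbor branching complexity.
#'
#' @param profile a [sholl_profile()].
#' @return integer total.
#' @export
total_intersections <- function(profile) {
  stopifnot(inherits(profile, "sholl_profile"))
  sum(profile$counts)
}

#' Terminal-to-primary branch ratio
#'
#' Number of terminal branch endings (skeleton endpoints not adjacent to
#' the soma and not on the image border) divided by the number of primary
#' processes (8-connected clusters of skeleton pixels adjacent to the soma
#' boundary). A cell with zero primaries is uninterpretable and raises an
#' error (such cells are excluded upstream, mirroring the quality
#' exclusions applied to sectioning-artifact cells).
#'
#' @param skeleton a `skeleton` object built with a soma mask.
#' @return dimensionless ratio.
#' @export
terminal_primary_ratio <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton"))
  n_prim <- count_primaries(skeleton)
  if (n_prim == 0)
    stop("zero primary processes: terminal-to-primary ratio undefined")
  term <- terminal_endpoints(skeleton)
  nrow(term) / n_prim
}

## primaries = 8-connected clusters of soma-attachment pixels
count_primaries <- function(skeleton) {
  atts <- skeleton$attachments
  if (is.null(atts) || !nrow(atts)) return(0L)
  count_point_components8(atts)
}

## endpoints that are neither soma-adjacent nor on the image border
terminal_endpoints <- function(skeleton) {
  eps <- skeleton$endpoints
  if (!nrow(eps)) return(eps)
  shape <- dim(skeleton$mask)
  on_border <- eps[, 1] == 1 | eps[, 1] == shape[1] |
    eps[, 2] == 1 | eps[, 2] == shape[2]
  near_soma <- rep(FALSE, nrow(eps))
  if (!is.null(skeleton$soma_mask) && any(skeleton$soma_mask)) {
    dil <- binary_dilate(skeleton$soma_mask != 0, SOMA_ATTACH_DIST)
    near_soma <- dil[eps]
  }
  eps[!on_border & !near_soma, , drop = FALSE]
}

#' Estimated cell territory size
#'
#' Area of the circle enclosed by the last Sholl intersection radius
#' (measured from the soma center): `pi * r^2`.
#'
#' @param last_radius_um last intersection radius in um (`>= 0`).
#' @return area in um^2.
#' @examples
#' territory_size(35)  # pi * 35^2
#' @export
territory_size <- function(last_radius_um) {
  stopifnot(last_radius_um >= 0)
  pi * last_radius_um^2
}

#' Compute the six-metric vector for one cell
#'
#' Aggregates the six descriptors; the length-to-soma ratio is always
#' computed from the two component metrics, never independently. Component
#' errors (empty soma, zero primaries) propagate.
#'
#' @param seg a `segmentation_result`.
#' @param skeleton the `skeleton` of `seg$process_mask`.
#' @param profile the [sholl_profile()] of that skeleton.
#' @param microns_per_px calibration (`> 0`).
#' @param cell_id,group,compartment metadata carried into the output.
#' @return an object of class `metric_vector` (a one-row data.frame with
#'   the six metric columns plus metadata and provenance columns
#'   `sholl_mode`, `sholl_interval_px`, `microns_per_px`).
#' @export
compute_metric_vector <- function(seg, skeleton, profile, microns_per_px,
                                  cell_id = NA_character_,
                                  group = NA_character_,
                                  compartment = NA_character_) {
  stopifnot(inherits(seg, "segmentation_result"),
            inherits(skeleton, "skeleton"),
            inherits(profile, "sholl_profile"))
  soma <- soma_size(seg$soma_mask, microns_per_px)
  len <- max_process_length(skeleton, seg$soma_mask, profile, microns_per_px)
  tpr <- terminal_primary_ratio(skeleton)
  lir <- last_intersection_radius_um(profile, microns_per_px)
  out <- data.frame(
    cell_id = as.character(cell_id),
    group = as.character(group),
    compartment = as.character(compartment),
    max_process_length = len,
    total_intersections = total_intersections(profile),
    terminal_primary_ratio = tpr,
    soma_size = soma,
    length_soma_ratio = len / soma,
    territory_size = territory_size(lir),
    sholl_mode = profile$mode,
    sholl_interval_px = profile$interval,
    microns_per_px = microns_per_px,
    stringsAsFactors = FALSE)
  class(out) <- c("metric_vector", class(out))
  out
}

#' Full per-cell measurement from a single-cell image
#'
#' Convenience wrapper running segmentation, optional gap closing,
#' soma/process separation, skeletonization, Sholl profiling and the six
#' metrics in one call.
#'
#' @param image a [calibrated_image()].
#' @param threshold,use_watershed passed to [segment_cell()].
#' @param max_gap passed to [close_gaps()] on the process mask (0 = off).
#' @param interval,mode passed to [sholl_profile()].
#' @param soma_center_hint optional (row, col) passed to [separate_soma()].
#' @param cell_id metadata label (defaults to the image's case id).
#' @return a `metric_vector`; intermediate objects are attached as
#'   attributes `seg`, `skeleton`, `profile`.
#' @export
measure_cell <- function(image, threshold = "otsu", use_watershed = FALSE,
                         max_gap = 0, interval = 10,
                         mode = c("pixel", "run"),
                         soma_center_hint = NULL, cell_id = NULL) {
  mode <- match.arg(mode)
  cell <- segment_cell(image, threshold = threshold,
                       use_watershed = use_watershed)
  slack <- if (is.null(image$roi_scale)) 1 else image$roi_scale
  seg <- separate_soma(cell, soma_center_hint, boundary_slack = slack)
  proc <- seg$process_mask
  if (max_gap > 0) proc <- close_gaps(proc, max_gap)
  skel <- skeletonize_processes(proc, seg$soma_mask)
  prof <- sholl_profile(skel, seg$soma_center, interval = interval,
                        mode = mode)
  mv <- compute_metric_vector(seg, skel, prof, image$microns_per_px,
                              cell_id = if (is.null(cell_id)) image$case_id
                                        else cell_id,
                              group = image$group,
                              compartment = image$compartment)
  attr(mv, "seg") <- seg
  attr(mv, "skeleton") <- skel
  attr(mv, "profile") <- prof
  mv
}
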