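## Synthetic single-astrocyte phantoms, multi-cell counting fields, and
## metric-vector cohorts with exact, constructed ground truth. These stand in
## for DAB-stained GFAP+ cells so that segmentation, Sholl profiling,
## morphometrics and profiling can all be tested against known answers.

#' Canonical metric names, in fixed order
#'
#' The six descriptors of a single astrocyte: maximum process length (um),
#' total Sholl intersections (count), terminal-to-primary branch ratio,
#' soma size (um^2), length-to-soma ratio (1/um), estimated territory
#' size (um^2).
#' @return character vector of length 6.
#' @export
metric_names <- function() {
  c("max_process_length", "total_intersections", "terminal_primary_ratio",
    "soma_size", "length_soma_ratio", "territory_size")
}

#' Specification of a star-shaped astrocyte phantom
#'
#' Describes a filled-disc soma at the canvas center with `n_primaries`
#' arms leaving the soma outline at equally spaced angles (plus optional
#' angular jitter). Each arm may bifurcate symmetrically `branch_depth`
#' times; child segments shrink by `child_fraction` per generation.
#'
#' @param soma_radius soma disc radius in px (`>= 1`).
#' @param n_primaries number of primary processes (`>= 0`).
#' @param arm_length primary segment length in px (`>= 0`).
#' @param branch_depth bifurcation generations (0 = unbranched arms).
#' @param branch_angle full angle between sibling branches, degrees.
#' @param jitter dimensionless noise scale in `[0, 1]`: scales both the
#'   angular perturbation of arm placement (up to half the inter-arm
#'   spacing) and the intensity noise (`sd = 10 * jitter` gray levels).
#' @param microns_per_px calibration (default 0.25, a documented stand-in:
#'   the imaging calibration is study-specific and must be supplied for
#'   real data).
#' @param seed integer seed or `NULL`.
#' @param arm_thickness arm thickness in px, 1-3. The default 1 keeps
#'   skeletonization exact (the thinned skeleton is the drawn polyline);
#'   thicker arms exercise the robustness of thinning instead.
#' @param child_fraction length shrink factor per branching generation.
#' @param binary if `TRUE`, emit a 0/1 mask instead of 8-bit intensities.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(soma_radius = 10, n_primaries = 5, arm_length = 40,
                         branch_depth = 0, branch_angle = 40, jitter = 0,
                         microns_per_px = 0.25, seed = NULL,
                         arm_thickness = 1, child_fraction = 0.6,
                         binary = FALSE) {
  stopifnot(soma_radius >= 1, n_primaries >= 0, arm_length >= 0,
            branch_depth >= 0, microns_per_px > 0,
            arm_thickness %in% 1:3, jitter >= 0)
  structure(as.list(environment()), class = "phantom_spec")
}

## maximum possible radial reach of an arm system (all generations collinear)
phantom_reach <- function(spec) {
  if (spec$n_primaries == 0 || spec$arm_length == 0) return(spec$soma_radius)
  gen <- spec$arm_length * spec$child_fraction^(0:spec$branch_depth)
  spec$soma_radius + sum(gen)
}

#' Generate a star-shaped astrocyte phantom
#'
#' Draws the phantom directly as a raster; all truth fields are computed
#' from the same construction, so parameter-recovery tests are exact.
#'
#' @param spec a [phantom_spec()].
#' @param canvas optional (nrow, ncol); must contain the soma plus the full
#'   arm reach, otherwise an error is raised (never silent clipping). By
#'   default a tight odd-sided square canvas is chosen.
#' @return list with `image` (a [calibrated_image()]) and `truth`, a list
#'   with `soma_area` (px^2, raster-exact), `primary_count`,
#'   `terminal_count`, `max_reach` (px from soma center, from the
#'   continuous arm geometry), `center`, `arm_angles` (radians),
#'   `tip_radii`, and `mask` (the exact foreground raster).
#' @examples
#' ph <- make_star_astrocyte(phantom_spec(soma_radius = 10, n_primaries = 4,
#'                                        arm_length = 60))
#' ph$truth$max_reach  # 70
#' @export
make_star_astrocyte <- function(spec, canvas = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  reach <- phantom_reach(spec)
  need <- 2 * ceiling(reach + spec$arm_thickness + 3) + 1
  if (is.null(canvas)) canvas <- c(need, need)
  if (canvas[1] < need || canvas[2] < need)
    stop("canvas overflow: phantom reach ", round(reach, 1),
         " px needs at least ", need, " px per side")
  with_seed(spec$seed, {
    center <- c((canvas[1] + 1) / 2, (canvas[2] + 1) / 2)
    mask <- matrix(FALSE, canvas[1], canvas[2])
    soma_px <- disc_pixels(center, spec$soma_radius, canvas)
    mask <- set_pixels(mask, soma_px, TRUE)

    tips <- list(); angles <- numeric(0)
    if (spec$n_primaries > 0 && spec$arm_length > 0) {
      spacing <- 2 * pi / spec$n_primaries
      angles <- (seq_len(spec$n_primaries) - 1) * spacing +
        spec$jitter * runif(spec$n_primaries, -0.5, 0.5) * spacing
      arm <- matrix(FALSE, canvas[1], canvas[2])
      for (a in angles) {
        res <- draw_branch(arm, center, a,
                           start_r = spec$soma_radius,
                           len = spec$arm_length,
                           depth = spec$branch_depth,
                           branch_angle = spec$branch_angle * pi / 180,
                           child_fraction = spec$child_fraction,
                           thickness = spec$arm_thickness)
        arm <- res$mask
        tips <- c(tips, res$tips)
      }
      mask <- mask | arm
    }
    tip_radii <- if (length(tips))
      vapply(tips, function(p) sqrt(sum((p - center)^2)), 0) else numeric(0)
    truth <- list(
      soma_area = nrow(soma_px),
      primary_count = if (spec$arm_length > 0) spec$n_primaries else 0L,
      terminal_count = if (spec$arm_length > 0 && spec$n_primaries > 0)
        as.integer(spec$n_primaries * 2^spec$branch_depth) else 0L,
      max_reach = max(spec$soma_radius, if (length(tip_radii)) max(tip_radii) else 0),
      center = center,
      arm_angles = angles,
      tip_radii = tip_radii,
      mask = mask)
    px <- if (spec$binary) {
      matrix(as.numeric(mask), canvas[1], canvas[2])
    } else {
      img <- matrix(30, canvas[1], canvas[2])
      img[mask] <- 200
      if (spec$jitter > 0)
        img <- img + matrix(rnorm(length(img), 0, 10 * spec$jitter),
                            canvas[1], canvas[2])
      pmin(pmax(round(img), 0), 255)
    }
    list(image = calibrated_image(px, spec$microns_per_px), truth = truth)
  })
}

## Recursively draw one arm starting on the soma outline. Returns the updated
## mask and the list of terminal tip coordinates (continuous geometry).
draw_branch <- function(mask, center, angle, start_r, len, depth,
                        branch_angle, child_fraction, thickness) {
  # draw from 1 px inside the soma outline for a solid attachment, but the
  # nominal arm spans [start_r, start_r + len] so tips land exactly at
  # soma_radius + arm_length
  start <- center + (start_r - 1) * c(-cos(angle), sin(angle))
  seg_end <- center + (start_r + len) * c(-cos(angle), sin(angle))
  mask <- draw_segment(mask, start, seg_end, thickness)
  if (depth == 0) return(list(mask = mask, tips = list(seg_end)))
  tips <- list()
  end_r <- start_r + len
  for (da in c(-branch_angle / 2, branch_angle / 2)) {
    child <- draw_branch_from(mask, seg_end, angle + da, len * child_fraction,
                              depth - 1, branch_angle, child_fraction,
                              thickness)
    mask <- child$mask
    tips <- c(tips, child$tips)
  }
  list(mask = mask, tips = tips)
}

draw_branch_from <- function(mask, start, angle, len, depth, branch_angle,
                             child_fraction, thickness) {
  seg_end <- start + len * c(-cos(angle), sin(angle))
  mask <- draw_segment(mask, start, seg_end, thickness)
  if (depth == 0) return(list(mask = mask, tips = list(seg_end)))
  tips <- list()
  for (da in c(-branch_angle / 2, branch_angle / 2)) {
    child <- draw_branch_from(mask, seg_end, angle + da, len * child_fraction,
                              depth - 1, branch_angle, child_fraction,
                              thickness)
    mask <- child$mask
    tips <- c(tips, child$tips)
  }
  list(mask = mask, tips = tips)
}

## Thickness 1: Bresenham line. 2: line plus a 1-px perpendicular offset
## copy. 3: line dilated by a radius-1 disc.
draw_segment <- function(mask, p0, p1, thickness) {
  px <- bresenham_line(p0[1], p0[2], p1[1], p1[2])
  px <- px[px[, 1] >= 1 & px[, 1] <= nrow(mask) &
             px[, 2] >= 1 & px[, 2] <= ncol(mask), , drop = FALSE]
  mask <- set_pixels(mask, px, TRUE)
  if (thickness >= 2 && nrow(px)) {
    d <- p1 - p0
    # offset along the non-dominant axis: keeps the doubled line a clean
    # 2-px band (a diagonal offset would leave a checkerboard that thins
    # into loops)
    perp <- if (abs(d[1]) >= abs(d[2])) c(0L, 1L) else c(1L, 0L)
    shifted <- cbind(px[, 1] + perp[1], px[, 2] + perp[2])
    shifted <- shifted[shifted[, 1] >= 1 & shifted[, 1] <= nrow(mask) &
                         shifted[, 2] >= 1 & shifted[, 2] <= ncol(mask), ,
                       drop = FALSE]
    mask <- set_pixels(mask, shifted, TRUE)
    if (thickness == 3) {
      shifted2 <- cbind(px[, 1] - perp[1], px[, 2] - perp[2])
      shifted2 <- shifted2[shifted2[, 1] >= 1 & shifted2[, 1] <= nrow(mask) &
                             shifted2[, 2] >= 1 & shifted2[, 2] <= ncol(mask), ,
                           drop = FALSE]
      mask <- set_pixels(mask, shifted2, TRUE)
    }
  }
  mask
}

#' Generate a multi-cell counting field with a planted cell count
#'
#' Places `n_cells` small star phantoms on a field canvas without mask
#' overlap and with pairwise center separation at least `min_separation`.
#' The canvas side is derived from the physical field area and the
#' calibration (the published counting fields cover about 0.159 mm^2).
#'
#' @param n_cells number of cells to plant (`>= 0`).
#' @param min_separation minimum pairwise center distance, px.
#' @param field_area physical field area in mm^2 (default 0.159).
#' @param seed integer seed or `NULL`.
#' @param microns_per_px calibration; the default 1.0 um/px keeps the
#'   0.159 mm^2 field at a ~400 px side, appropriate for counting (not
#'   single-cell morphometry).
#' @param cell_spec [phantom_spec()] for the planted cells (soma radius 5,
#'   4 arms of 12 px by default).
#' @param max_tries placement attempts per cell before giving up.
#' @return list with `image` (a [calibrated_image()]) and `truth`
#'   (`planted_cell_count`, `centers`, `mask`).
#' @export
make_field_image <- function(n_cells, min_separation = 45,
                             field_area = 0.159, seed = NULL,
                             microns_per_px = 1.0,
                             cell_spec = phantom_spec(soma_radius = 5,
                                                      n_primaries = 4,
                                                      arm_length = 12,
                                                      jitter = 0),
                             max_tries = 200L) {
  stopifnot(n_cells >= 0, min_separation >= 0, field_area > 0)
  side <- round(sqrt(field_area * 1e6) / microns_per_px)
  pad <- ceiling(phantom_reach(cell_spec)) + cell_spec$arm_thickness + 3
  if (side < 2 * pad + 1 && n_cells > 0)
    stop("field canvas (", side, " px) too small for the cell phantom")
  with_seed(seed, {
    mask <- matrix(FALSE, side, side)
    centers <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        ctr <- c(runif(1, pad + 1, side - pad), runif(1, pad + 1, side - pad))
        ok <- !nrow(centers) ||
          min(sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2)) >=
            min_separation
        if (ok) { centers <- rbind(centers, ctr); placed <- TRUE; break }
      }
      if (!placed)
        stop("infeasible placement: could not place cell ", i, " of ",
             n_cells, " after ", max_tries, " tries")
    }
    # draw each phantom with jittered arm angles (per-cell sub-seed drawn
    # from this stream) and paste onto the field
    for (i in seq_len(nrow(centers))) {
      sp <- cell_spec
      sp$jitter <- max(sp$jitter, 0.5)  # vary arm angles between cells
      sp$seed <- sample.int(.Machine$integer.max, 1)
      ph <- make_star_astrocyte(sp)
      pm <- ph$truth$mask
      r0 <- round(centers[i, 1] - ph$truth$center[1])
      c0 <- round(centers[i, 2] - ph$truth$center[2])
      idx <- which(pm, arr.ind = TRUE)
      idx[, 1] <- idx[, 1] + r0
      idx[, 2] <- idx[, 2] + c0
      keep <- idx[, 1] >= 1 & idx[, 1] <= side & idx[, 2] >= 1 & idx[, 2] <= side
      mask <- set_pixels(mask, idx[keep, , drop = FALSE], TRUE)
    }
    px <- matrix(30, side, side)
    px[mask] <- 200
    if (cell_spec$jitter > 0 && !cell_spec$binary)
      px <- pmin(pmax(round(px + matrix(rnorm(length(px), 0,
                                              10 * cell_spec$jitter),
                                        side, side)), 0), 255)
    truth <- list(planted_cell_count = as.integer(n_cells),
                  centers = centers, mask = mask)
    list(image = calibrated_image(px, microns_per_px), truth = truth)
  })
}

# ---------------------------------------------------------------------------
# Reference values: global medians and per-profile medians reported for the
# 36-cell striatal astrocyte cohort, used as distribution centers for
# synthetic metric cohorts and as consistency fixtures.
# ---------------------------------------------------------------------------

#' Published global medians of the six metrics
#'
#' Pooled over compartments and groups. Units: um, count, ratio, um^2,
#' 1/um, um^2 (in [metric_names()] order).
#' @return named numeric vector of length 6.
#' @export
reference_global_medians <- function() {
  setNames(c(33, 1783, 1.96, 118.8, 0.25, 253.5), metric_names())
}

#' Published global interquartile ranges of the six metrics
#' @return 2 x 6 matrix (rows: q25, q75).
#' @export
reference_global_iqr <- function() {
  m <- rbind(q25 = c(22.86, 910.25, 1.30, 89.70, 0.13, 209.46),
             q75 = c(36.78, 3183, 2.19, 165.72, 0.37, 424.22))
  colnames(m) <- metric_names()
  m
}

#' Published per-profile medians (NA where not reported)
#'
#' Six rows (profiles 1-6), six columns ([metric_names()]). Only the
#' reported (profile, metric) medians are filled; the terminal-to-primary
#' ratio was not reported per profile, nor the length-to-soma ratio for
#' profiles 1-3.
#' @return 6 x 6 numeric matrix.
#' @export
reference_profile_medians <- function() {
  m <- rbind(
    c(20.3,  918, NA, 115.10, NA, 220.5),
    c(16.8,  522, NA, 202.60, NA, 240.8),
    c(36.4, 3425, NA, 184.20, NA, 512.2),
    c(34.0, 3385, NA, 103.90, 0.4, 382.5),
    c(28.9, 1724, NA,  69.85, 0.5, 189.0),
    c(39.9, 2888, NA, 109.90, 0.4, 327.0))
  dimnames(m) <- list(profile = 1:6, metric = metric_names())
  m
}

#' Above/below-median signature of each morphometric profile
#'
#' The six recurrent profiles, each summarized as above (`"above"`) or
#' below (`"below"`) the global median on each metric. Profiles 4 and 6
#' share a pattern and are distinguished only by a disambiguation rule
#' (see [assign_profile()]).
#' @return 6 x 6 character matrix of `"above"`/`"below"`.
#' @export
profile_signatures <- function() {
  A <- "above"; B <- "below"
  m <- rbind(
    c(B, B, B, B, B, B),   # 1: compact, low arbor
    c(B, B, B, A, B, B),   # 2: soma-dominant
    c(A, A, B, A, A, B),   # 3: large soma + large arbor
    c(A, A, A, B, A, A),   # 4: process-dominant, dense branching
    c(B, B, B, B, B, A),   # 5: smallest soma, relatively long processes
    c(A, A, A, B, A, A))   # 6: process-dominant, long radial reach
  dimnames(m) <- list(profile = 1:6,
                      metric = c("max_process_length", "total_intersections",
                                 "terminal_primary_ratio", "soma_size",
                                 "territory_size", "length_soma_ratio"))
  # reorder columns to canonical metric order
  m[, metric_names()]
}

## Distribution centers for cohort generation: published medians where
## available; otherwise values consistent with the profile's side of the
## global median (below -> 0.8x, above -> 1.25x global), flagged imputed.
## Length-to-soma centers for profiles 1-3 derive from the published
## length and soma medians (their ratios fall below the global median,
## matching the signature table).
profile_generation_centers <- function() {
  centers <- reference_profile_medians()
  gm <- reference_global_medians()
  sig <- profile_signatures()
  imputed <- is.na(centers)
  for (p in 1:6) {
    if (is.na(centers[p, "length_soma_ratio"]))
      centers[p, "length_soma_ratio"] <-
        centers[p, "max_process_length"] / centers[p, "soma_size"]
    for (mname in metric_names())
      if (is.na(centers[p, mname]))
        centers[p, mname] <- gm[mname] *
          if (sig[p, mname] == "above") 1.25 else 0.8
  }
  attr(centers, "imputed") <- imputed
  centers
}

#' Generate a cohort of metric vectors with known profile membership
#'
#' Draws each cell's six metrics independently from log-normal
#' distributions whose medians are the published per-profile medians
#' (imputed from the profile's side of the global median where no value
#' was published). The vectors are statistical stand-ins: they are not
#' geometrically consistent single cells.
#'
#' @param profile_mix named list/vector mapping profile id (1-6) to the
#'   number of cells to draw, e.g. `c("1" = 5, "4" = 3)`.
#' @param seed integer seed or `NULL`.
#' @param sigma log-scale standard deviation of the perturbation
#'   (0 = exact medians; default 0.15, a mild within-profile spread).
#' @return data.frame with `cell_id`, `true_profile`, and the six metric
#'   columns in [metric_names()] order.
#' @export
make_metric_cohort <- function(profile_mix, seed = NULL, sigma = 0.15) {
  ids <- as.integer(names(profile_mix))
  if (is.null(names(profile_mix)) && length(profile_mix) == 6)
    ids <- 1:6
  stopifnot(all(ids %in% 1:6), all(profile_mix >= 0))
  centers <- profile_generation_centers()
  with_seed(seed, {
    rows <- list()
    n_total <- 0L
    for (j in seq_along(ids)) {
      p <- ids[j]
      n <- as.integer(profile_mix[[j]])
      if (n == 0) next
      draw <- matrix(rep(centers[p, ], each = n), nrow = n,
                     dimnames = list(NULL, metric_names()))
      if (sigma > 0)
        draw <- draw * exp(matrix(rnorm(n * 6, 0, sigma), n, 6))
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = sprintf("P%d_%03d", p, seq_len(n) + n_total),
        true_profile = p, draw, check.names = FALSE)
      n_total <- n_total + n
    }
    if (!length(rows))
      return(data.frame(cell_id = character(0), true_profile = integer(0)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write a phantom image and its ground-truth sidecar
#'
#' Writes the image as an 8-bit TIFF and the truth record (minus the raster
#' mask) plus the generating spec as a sidecar JSON next to it.
#'
#' @param phantom a list as returned by [make_star_astrocyte()] or
#'   [make_field_image()].
#' @param path output TIFF path; the JSON goes to `<path>.json`.
#' @param spec optional generating spec to record.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path, spec = NULL) {
  write_tiff_gray(phantom$image, path)
  truth <- phantom$truth
  truth$mask <- NULL
  rec <- list(truth = truth,
              microns_per_px = phantom$image$microns_per_px,
              spec = if (!is.null(spec)) unclass(spec))
  jsonlite::write_json(rec, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
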