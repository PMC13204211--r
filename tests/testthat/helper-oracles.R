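# Shared fixtures and independent oracles. Oracles are deliberately written
# from the definitions (loops, enumeration, geometry), not by calling the
# implementation paths they check.

# Geometric ring-crossing oracle for radial-arm star phantoms: a straight
# radial arm spanning [start_r, tip_r] crosses the circle of radius R once
# iff start_r < R < tip_r (tangency at the exact endpoints excluded).
oracle_star_ring_count <- function(R, start_r, tip_radii) {
  sum(start_r < R & R < tip_radii)
}

# Literal two-stage BKY step-up, straight from the published definition.
bky_oracle <- function(p, alpha) {
  m <- length(p)
  ap <- alpha / (1 + alpha)
  bh_count <- function(pv, a) {
    ps <- sort(pv)
    ok <- which(ps <= seq_len(m) * a / m)
    if (length(ok)) max(ok) else 0L
  }
  r1 <- bh_count(p, ap)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  m0 <- m - r1
  k <- bh_count(p, ap * m / m0)
  if (k == 0) return(rep(FALSE, m))
  p <= sort(p)[k]
}

# Neighbor-count oracle over all skeleton pixels: plain double loop.
oracle_neighbor_counts <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    n <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && mask[rr, cc])
        n <- n + 1
    }
    out <- rbind(out, c(r, c, n))
  }
  out
}

# global_medians object carrying the published reference values
reference_medians_object <- function() {
  structure(list(medians = reference_global_medians(),
                 iqr = reference_global_iqr(), n = 36L),
            class = "global_medians")
}

# deterministic pseudo-random sparse skeleton on a small grid
random_skeleton <- function(side = 40, n_px = 80) {
  m <- matrix(FALSE, side, side)
  idx <- sample.int(side * side, n_px)
  m[idx] <- TRUE
  # a couple of random line segments for connected structure
  for (i in 1:3) {
    p <- sample.int(side, 4)
    m <- set_px(m, bresenham_line(p[1], p[2], p[3], p[4]))
  }
  m
}

set_px <- function(m, px) {
  m[cbind(px[, 1], px[, 2])] <- TRUE
  m
}

# grayscale image from a logical mask with the phantom intensity model
mask_to_image <- function(mask, microns_per_px = 0.25) {
  px <- matrix(30, nrow(mask), ncol(mask))
  px[mask] <- 200
  calibrated_image(px, microns_per_px)
}
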