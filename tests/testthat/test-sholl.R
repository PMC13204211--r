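# sholl_engine: skeletonization, ring rasterization, intersection profiles

test_that("skeleton classification matches the neighbor-count oracle", {
  # empty mask
  sk0 <- skeletonize_processes(matrix(FALSE, 20, 20))
  expect_equal(sum(sk0$mask), 0)
  expect_equal(nrow(sk0$endpoints), 0L)

  # straight 2-px-thick arm -> 1-px path, 2 endpoints, 0 branch points
  m <- matrix(FALSE, 40, 40)
  m[10:30, 20] <- TRUE
  m[10:30, 21] <- TRUE
  sk <- skeletonize_processes(m)
  nb <- oracle_neighbor_counts(sk$mask)
  expect_equal(sum(nb[, 3] == 1), 2)
  expect_equal(sum(nb[, 3] >= 3), 0)
  expect_equal(nrow(sk$endpoints), 2L)
  expect_equal(nrow(sk$branch_points), 0L)

  # symmetric Y: 3 endpoints, 1 branch point (oracle-checked)
  y <- matrix(FALSE, 50, 50)
  y <- set_px(y, bresenham_line(40, 25, 25, 25))
  y <- set_px(y, bresenham_line(25, 25, 10, 15))
  y <- set_px(y, bresenham_line(25, 25, 10, 35))
  sky <- skeletonize_processes(y)
  nby <- oracle_neighbor_counts(sky$mask)
  expect_equal(sum(nby[, 3] == 1), 3)
  expect_equal(nrow(sky$endpoints), 3L)
  expect_gte(nrow(sky$branch_points), 1L)
})

test_that("ring rasterization is a closed clipped digital circle", {
  # radius 1: the full 8-neighborhood (supercover dialect)
  r1 <- rasterize_ring(c(10, 10), 1, c(20, 20))
  expect_equal(sum(r1), 8)
  expect_false(r1[10, 10])

  # rings fully inside the grid form one closed curve separating the plane
  for (r in c(3, 7.5, 15)) {
    ring <- rasterize_ring(c(40, 40), r, c(80, 80))
    expect_equal(max(label_components(ring, 8)), 1L)
    # closed under 4-connectivity: complement splits into inside + outside
    expect_equal(max(label_components(!ring, 4)), 2L)
  }

  # clipped near the border: no out-of-bounds, still some pixels
  edge <- rasterize_ring(c(2, 2), 10, c(30, 30))
  expect_true(any(edge))
  expect_equal(dim(edge), c(30, 30))
})

test_that("star phantoms yield exactly k crossings per interior ring", {
  ph <- make_star_astrocyte(phantom_spec(soma_radius = 10, n_primaries = 4,
                                         arm_length = 60, jitter = 0))
  seg <- separate_soma(segment_cell(ph$image))
  sk <- skeletonize_processes(seg$process_mask, seg$soma_mask)
  run <- sholl_profile(sk, seg$soma_center, interval = 10, mode = "run")
  pix <- sholl_profile(sk, seg$soma_center, interval = 10, mode = "pixel")
  interior <- run$radii > 10 & run$radii < 70
  expect_true(all(run$counts[interior] == 4))
  expect_true(all(run$counts[run$radii > 70 + 1] == 0))
  # pixel mode dominates run mode everywhere
  expect_true(all(pix$counts >= run$counts))
  expect_equal(run$last_intersection_radius, 70)
})

test_that("a single radial arm crosses once at every interior ring (100 angles)", {
  set.seed(31)
  for (i in 1:100) {
    L <- sample(20:100, 1)
    ph <- make_star_astrocyte(phantom_spec(soma_radius = 10, n_primaries = 1,
                                           arm_length = L, jitter = 1,
                                           seed = i))
    seg <- separate_soma(segment_cell(ph$image))
    sk <- skeletonize_processes(seg$process_mask, seg$soma_mask)
    run <- sholl_profile(sk, seg$soma_center, interval = 10, mode = "run")
    interior <- run$radii > 10 & run$radii < 10 + L
    expect_true(all(run$counts[interior] == 1),
                info = sprintf("angle rep %d, L %d: %s", i, L,
                               paste(run$counts[interior], collapse = ",")))
  }
})

test_that("rotating the grid by 90 degrees preserves totals", {
  ph <- make_star_astrocyte(phantom_spec(soma_radius = 9, n_primaries = 5,
                                         arm_length = 45, jitter = 0.7,
                                         seed = 12))
  seg <- separate_soma(segment_cell(ph$image))
  sk <- skeletonize_processes(seg$process_mask, seg$soma_mask)
  for (mode in c("run", "pixel")) {
    p1 <- sholl_profile(sk, seg$soma_center, 10, mode)
    rot <- mask_to_image(apply(t(ph$truth$mask), 1, rev))  # 90 deg rotation
    segr <- separate_soma(segment_cell(rot))
    skr <- skeletonize_processes(segr$process_mask, segr$soma_mask)
    p2 <- sholl_profile(skr, segr$soma_center, 10, mode)
    expect_equal(sum(p2$counts), sum(p1$counts))
  }
})

test_that("ring counts have no hidden state across enumeration order", {
  set.seed(17)
  sk <- random_skeleton(60, 120)
  prof <- sholl_profile(sk, c(30, 30), interval = 5, mode = "pixel")
  # recompute each ring independently via rasterize_ring
  for (i in seq_along(prof$radii)) {
    ring <- rasterize_ring(c(30, 30), prof$radii[i], dim(sk))
    expect_equal(prof$counts[i], sum(sk & ring))
  }
})

test_that("last intersection radius converts linearly to micrometers", {
  prof <- structure(list(center = c(1, 1), interval = 10, mode = "run",
                         radii = c(10, 20), counts = c(1L, 0L),
                         last_intersection_radius = 10),
                    class = "sholl_profile")
  expect_equal(last_intersection_radius_um(prof, 0.5), 5)
  expect_equal(last_intersection_radius_um(prof, 1.0), 10)
  prof$last_intersection_radius <- 0
  expect_equal(last_intersection_radius_um(prof, 0.5), 0)
})

test_that("sholl profiles serialize to CSV with a JSON header", {
  td <- withr::local_tempdir()
  ph <- make_star_astrocyte(phantom_spec(n_primaries = 3, arm_length = 30))
  seg <- separate_soma(segment_cell(ph$image))
  sk <- skeletonize_processes(seg$process_mask, seg$soma_mask)
  prof <- sholl_profile(sk, seg$soma_center)
  p <- file.path(td, "prof.csv")
  write_sholl_profile(prof, p, 0.25)
  df <- read.csv(p)
  expect_named(df, c("radius_px", "radius_um", "count"))
  expect_equal(df$count, prof$counts)
  hdr <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(hdr$interval_px, 10)
  expect_equal(hdr$mode, "pixel")
})
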