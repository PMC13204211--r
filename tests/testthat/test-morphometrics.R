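# morphometrics: the six descriptors and their aggregation

test_that("soma size is calibrated pixel counting", {
  m <- matrix(FALSE, 30, 30)
  m[1:20, 1:20] <- TRUE  # 400 px
  expect_equal(soma_size(m, 0.5), 100)
  expect_error(soma_size(matrix(FALSE, 5, 5), 1), "empty soma")
  tiny <- matrix(FALSE, 5, 5); tiny[3, 3] <- TRUE
  expect_warning(expect_equal(soma_size(tiny, 1), 1), "small soma")

  # rasterized disc within 5% of pi r^2
  ph <- make_star_astrocyte(phantom_spec(soma_radius = 10, n_primaries = 0))
  seg <- separate_soma(ph$truth$mask)
  expect_lte(abs(soma_size(seg$soma_mask, 0.5) - pi * 10^2 * 0.25) /
               (pi * 25), 0.05)
})

test_that("max process length tracks the longest arm within one ring interval", {
  cal <- 0.25
  ph <- make_star_astrocyte(phantom_spec(soma_radius = 10, n_primaries = 1,
                                         arm_length = 57, jitter = 1,
                                         seed = 2))
  mv <- measure_cell(ph$image, interval = 10)
  # truth: 57 px = 14.25 um; quantized to the last ring => within one
  # interval (10 px = 2.5 um)
  expect_lte(abs(mv$max_process_length - 57 * cal), 10 * cal)

  # two arms 30 and 60 px: the longer arm defines the last ring
  m <- matrix(FALSE, 161, 161)
  m <- set_px(m, disc_pixels(c(81, 81), 10, c(161, 161)))
  m <- set_px(m, bresenham_line(81, 90, 81, 141))   # 60 px arm, east
  m <- set_px(m, bresenham_line(81, 72, 81, 42))    # 30 px arm, west
  mv2 <- measure_cell(mask_to_image(m, cal), interval = 10)
  # within one ring interval plus the soma-boundary regularization (~2 px)
  # of the long arm, and clearly governed by it (not the 30 px arm)
  expect_gte(mv2$max_process_length, (60 - 12) * cal)
  expect_lte(mv2$max_process_length, (60 + 2) * cal)
})

test_that("empty skeleton yields zero length with a warning", {
  ph <- make_star_astrocyte(phantom_spec(soma_radius = 10, n_primaries = 0))
  seg <- separate_soma(ph$truth$mask)
  sk <- skeletonize_processes(seg$process_mask, seg$soma_mask)
  prof <- sholl_profile(sk, seg$soma_center)
  expect_warning(
    expect_equal(max_process_length(sk, seg$soma_mask, prof, 0.25), 0),
    "empty skeleton|no Sholl")
})

test_that("total intersections sums the profile and equals the run oracle", {
  # soma 12, four arms of 65: tips at 77, interior rings 20..70
  ph <- make_star_astrocyte(phantom_spec(soma_radius = 12, n_primaries = 4,
                                         arm_length = 65, jitter = 0.3,
                                         seed = 5))
  seg <- separate_soma(segment_cell(ph$image))
  sk <- skeletonize_processes(seg$process_mask, seg$soma_mask)
  run <- sholl_profile(sk, seg$soma_center, 10, "run")
  # geometric oracle per ring
  oracle <- vapply(run$radii, oracle_star_ring_count, 0,
                   start_r = 12, tip_radii = ph$truth$tip_radii)
  expect_equal(run$counts, as.integer(oracle))
  expect_equal(total_intersections(run), 24)

  pix <- sholl_profile(sk, seg$soma_center, 10, "pixel")
  expect_gte(total_intersections(pix), total_intersections(run))
})

test_that("terminal-to-primary ratio is exact on constructed arbors", {
  ph4 <- make_star_astrocyte(phantom_spec(soma_radius = 10, n_primaries = 4,
                                          arm_length = 40, jitter = 0.3,
                                          seed = 3))
  seg <- separate_soma(segment_cell(ph4$image))
  sk <- skeletonize_processes(seg$process_mask, seg$soma_mask)
  expect_equal(terminal_primary_ratio(sk), 1.0)

  ph6 <- make_star_astrocyte(phantom_spec(soma_radius = 10, n_primaries = 3,
                                          arm_length = 40, branch_depth = 1,
                                          jitter = 0.3, seed = 4))
  seg6 <- separate_soma(segment_cell(ph6$image))
  sk6 <- skeletonize_processes(seg6$process_mask, seg6$soma_mask)
  expect_equal(terminal_primary_ratio(sk6), 2.0)

  # soma-only cell: undefined, explicit error
  ph0 <- make_star_astrocyte(phantom_spec(soma_radius = 10, n_primaries = 0))
  seg0 <- separate_soma(ph0$truth$mask)
  sk0 <- skeletonize_processes(seg0$process_mask, seg0$soma_mask)
  expect_error(terminal_primary_ratio(sk0), "zero primary")
})

test_that("territory size is the closed-form circle area", {
  expect_equal(territory_size(0), 0)
  expect_equal(territory_size(35), pi * 35^2)
  expect_equal(territory_size(70), 4 * territory_size(35))
  expect_error(territory_size(-1))
})

test_that("the metric vector is internally consistent", {
  ph <- make_star_astrocyte(phantom_spec(soma_radius = 10, n_primaries = 5,
                                         arm_length = 50, jitter = 0.4,
                                         seed = 9))
  mv <- measure_cell(ph$image)
  expect_s3_class(mv, "metric_vector")
  expect_equal(mv$length_soma_ratio, mv$max_process_length / mv$soma_size)
  prof <- attr(mv, "profile")
  expect_equal(mv$territory_size,
               pi * (prof$last_intersection_radius * 0.25)^2)
  expect_true(all(unlist(mv[metric_names()]) >= 0))

  # soma-only phantom: the component error propagates
  ph0 <- make_star_astrocyte(phantom_spec(soma_radius = 10, n_primaries = 0))
  expect_error(suppressWarnings(measure_cell(ph0$image)), "zero primary")
})

test_that("metrics are invariant under translation of the cell", {
  ph <- make_star_astrocyte(phantom_spec(soma_radius = 9, n_primaries = 4,
                                         arm_length = 35, jitter = 0.5,
                                         seed = 6))
  m <- ph$truth$mask
  pad <- 30
  big <- matrix(FALSE, nrow(m) + pad, ncol(m) + pad)
  big[1:nrow(m), 1:ncol(m)] <- m                      # top-left placement
  big2 <- matrix(FALSE, nrow(m) + pad, ncol(m) + pad)
  big2[pad + 1:nrow(m), pad + 1:ncol(m)] <- m          # bottom-right
  mv1 <- measure_cell(mask_to_image(big))
  mv2 <- measure_cell(mask_to_image(big2))
  for (f in metric_names())
    expect_equal(mv1[[f]], mv2[[f]], info = f)
})

test_that("territory radius bounds max process length on phantoms", {
  set.seed(44)
  for (i in 1:8) {
    sr <- sample(8:12, 1)
    ph <- make_star_astrocyte(phantom_spec(soma_radius = sr,
                                           n_primaries = sample(3:6, 1),
                                           arm_length = sample(30:80, 1),
                                           jitter = 0.4, seed = i))
    mv <- measure_cell(ph$image)
    terr_radius <- sqrt(mv$territory_size / pi)
    expect_gte(terr_radius,
               mv$max_process_length - (sr + 10) * 0.25)
  }
})
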