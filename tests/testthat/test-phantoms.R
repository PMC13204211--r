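# synthetic_data: phantom construction, exact ground truth, seed contract

test_that("star phantom truths are forced by construction", {
  # degenerate: soma only
  ph0 <- make_star_astrocyte(phantom_spec(soma_radius = 8, n_primaries = 0))
  expect_equal(ph0$truth$primary_count, 0)
  expect_equal(ph0$truth$terminal_count, 0L)
  expect_equal(ph0$truth$max_reach, 8)
  expect_equal(sum(ph0$truth$mask), ph0$truth$soma_area)

  # unbranched star
  ph <- make_star_astrocyte(phantom_spec(soma_radius = 10, n_primaries = 4,
                                         arm_length = 60))
  expect_equal(ph$truth$primary_count, 4)
  expect_equal(ph$truth$terminal_count, 4L)
  expect_equal(ph$truth$max_reach, 70)

  # symmetric bifurcation: 3 arms x 2 tips
  ph2 <- make_star_astrocyte(phantom_spec(n_primaries = 3, arm_length = 40,
                                          branch_depth = 1))
  expect_equal(ph2$truth$terminal_count, 6L)
})

test_that("soma truth is raster-exact", {
  for (r in c(5, 9, 14)) {
    ph <- make_star_astrocyte(phantom_spec(soma_radius = r, n_primaries = 0))
    ctr <- ph$truth$center
    # re-derive the disc area by counting pixels of the drawn raster
    d <- sqrt((row(ph$truth$mask) - ctr[1])^2 + (col(ph$truth$mask) - ctr[2])^2)
    expect_identical(sum(d <= r), as.integer(ph$truth$soma_area))
    expect_identical(sum(ph$truth$mask), as.integer(ph$truth$soma_area))
  }
})

test_that("same seed gives bit-identical phantoms, different seeds differ", {
  sp <- phantom_spec(n_primaries = 5, arm_length = 50, jitter = 0.4,
                     seed = 123)
  a <- make_star_astrocyte(sp)
  b <- make_star_astrocyte(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  sp2 <- sp; sp2$seed <- 124
  c <- make_star_astrocyte(sp2)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("canvas overflow raises instead of clipping", {
  expect_error(make_star_astrocyte(phantom_spec(soma_radius = 10,
                                                n_primaries = 4,
                                                arm_length = 60),
                                   canvas = c(100, 100)),
               "canvas overflow")
})

test_that("field images plant the stated number of separated cells", {
  f0 <- make_field_image(0, seed = 1)
  expect_equal(f0$truth$planted_cell_count, 0L)
  expect_false(any(f0$truth$mask))

  f7 <- make_field_image(7, min_separation = 60, seed = 2)
  expect_equal(f7$truth$planted_cell_count, 7L)
  # with separation above the cell diameter the union has exactly 7 pieces
  expect_equal(max(label_components(f7$truth$mask)), 7L)

  # seed contract: identical truth counts, different layouts
  fa <- make_field_image(5, seed = 10)
  fb <- make_field_image(5, seed = 11)
  expect_equal(fa$truth$planted_cell_count, fb$truth$planted_cell_count)
  expect_false(identical(fa$truth$centers, fb$truth$centers))
  expect_identical(fa$truth$centers,
                   make_field_image(5, seed = 10)$truth$centers)
})

test_that("infeasible placement errors after bounded retries", {
  expect_error(make_field_image(40, min_separation = 300, field_area = 0.02,
                                seed = 3, max_tries = 20),
               "infeasible placement")
})

test_that("metric cohorts reproduce the printed per-profile medians at zero noise", {
  coh1 <- make_metric_cohort(c("1" = 5), seed = 1, sigma = 0)
  expect_equal(nrow(coh1), 5)
  expect_true(all(coh1$max_process_length == 20.3))
  expect_true(all(coh1$total_intersections == 918))
  expect_true(all(coh1$soma_size == 115.1))
  expect_true(all(coh1$territory_size == 220.5))

  coh2 <- make_metric_cohort(c("2" = 10), seed = 1, sigma = 0)
  expect_true(all(coh2$soma_size == 202.6))

  # count conservation
  coh3 <- make_metric_cohort(c("1" = 3, "4" = 3), seed = 7, sigma = 0.3)
  expect_equal(nrow(coh3), 6)
  expect_equal(sort(unique(coh3$true_profile)), c(1, 4))
})

test_that("cohort noise is log-normal around the printed centers", {
  coh <- make_metric_cohort(c("3" = 400), seed = 42, sigma = 0.2)
  # median of log-normal perturbation equals the center
  expect_equal(median(coh$soma_size), 184.2, tolerance = 0.05)
  expect_true(all(coh[, metric_names()] > 0))
})

test_that("phantom sidecar JSON round-trips the truth record", {
  td <- withr::local_tempdir()
  ph <- make_star_astrocyte(phantom_spec(n_primaries = 4, arm_length = 30,
                                         seed = 1))
  p <- file.path(td, "cell.tif")
  write_phantom(ph, p, spec = phantom_spec(n_primaries = 4, arm_length = 30,
                                           seed = 1))
  rec <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(rec$truth$soma_area, ph$truth$soma_area)
  expect_equal(rec$truth$max_reach, ph$truth$max_reach)
  img <- read_tiff_gray(p, microns_per_px = rec$microns_per_px)
  expect_equal(img$pixels, ph$image$pixels, ignore_attr = TRUE)
})
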