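# segmentation: thresholding, watershed, gap closing, soma separation,
# field counting

test_that("fixed threshold on a binary phantom is the identity", {
  ph <- make_star_astrocyte(phantom_spec(n_primaries = 4, arm_length = 40,
                                         binary = TRUE))
  mask <- segment_cell(ph$image, threshold = 0.5)
  expect_identical(mask, ph$truth$mask)
})

test_that("Otsu recovers at least 99% of the phantom foreground", {
  ph <- make_star_astrocyte(phantom_spec(n_primaries = 5, arm_length = 50,
                                         jitter = 0.5, seed = 3))
  mask <- segment_cell(ph$image, threshold = "otsu")
  recovered <- sum(mask & ph$truth$mask) / sum(ph$truth$mask)
  expect_gte(recovered, 0.99)
})

test_that("only the center component is kept", {
  img <- matrix(30, 101, 101)
  m <- matrix(FALSE, 101, 101)
  m <- set_px(m, disc_pixels(c(51, 51), 8, c(101, 101)))   # cell A, centered
  m <- set_px(m, disc_pixels(c(15, 85), 8, c(101, 101)))   # cell B, corner
  img[m] <- 200
  mask <- segment_cell(calibrated_image(img, 0.25))
  expect_true(mask[51, 51])
  expect_false(mask[15, 85])
  expect_equal(max(label_components(mask)), 1L)
})

test_that("constant images raise a no-signal error", {
  img <- calibrated_image(matrix(30, 50, 50), 0.25)
  expect_error(segment_cell(img), "no signal")
})

test_that("watershed splits touching discs", {
  m <- matrix(FALSE, 80, 80)
  m <- set_px(m, disc_pixels(c(40, 30), 10, c(80, 80)))
  m <- set_px(m, disc_pixels(c(40, 46), 10, c(80, 80)))  # centers 16 px apart
  expect_equal(max(label_components(m)), 1L)  # touching: one blob
  split <- watershed_split(m)
  expect_equal(max(label_components(split)), 2L)
  # a lone disc is not oversplit
  single <- matrix(FALSE, 60, 60)
  single <- set_px(single, disc_pixels(c(30, 30), 10, c(60, 60)))
  expect_equal(max(label_components(watershed_split(single))), 1L)
})

test_that("close_gaps restores an interrupted arm without inventing branches", {
  ph <- make_star_astrocyte(phantom_spec(n_primaries = 1, arm_length = 50,
                                         arm_thickness = 2))
  mask <- ph$truth$mask
  # cut a 3-px break across the arm, 30 px above the center (arm 1 points up)
  ctr <- ph$truth$center
  rows <- (ctr[1] - 32):(ctr[1] - 30)
  mask[rows, ] <- FALSE
  expect_equal(max(label_components(mask)), 2L)
  healed <- close_gaps(mask, max_gap = 5)
  expect_equal(max(label_components(healed)), 1L)
  # no removal, bounded addition
  expect_true(all(healed[mask]))
  expect_lte(sum(healed) - sum(mask), 5)
})

test_that("close_gaps is the identity at max_gap 0 and ignores distant arms", {
  m <- matrix(FALSE, 60, 60)
  m[10:50, 10] <- TRUE
  m[10:50, 55] <- TRUE  # parallel arm 45 px away
  expect_identical(close_gaps(m, 0), m)
  expect_identical(close_gaps(m, 5), m)   # no candidate bridges
})

test_that("close_gaps never loses pixels nor splits components (property)", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_skeleton(50, 60)
    out <- close_gaps(m, max_gap = 6)
    expect_true(all(out[m]))
    expect_lte(max(label_components(out)), max(label_components(m)))
  }
})

test_that("separate_soma recovers disc and star somata", {
  # disc only
  ph <- make_star_astrocyte(phantom_spec(soma_radius = 12, n_primaries = 0))
  seg <- separate_soma(ph$truth$mask)
  expect_lte(abs(sum(seg$soma_mask) - ph$truth$soma_area) /
               ph$truth$soma_area, 0.05)
  expect_false(any(seg$process_mask))

  # star: arms excluded, soma within 10%
  ph2 <- make_star_astrocyte(phantom_spec(soma_radius = 10, n_primaries = 4,
                                          arm_length = 60,
                                          arm_thickness = 2))
  seg2 <- separate_soma(ph2$truth$mask)
  expect_lte(abs(sum(seg2$soma_mask) - ph2$truth$soma_area) /
               ph2$truth$soma_area, 0.10)
  ctr <- ph2$truth$center
  d <- sqrt((row(seg2$soma_mask) - ctr[1])^2 + (col(seg2$soma_mask) - ctr[2])^2)
  expect_lte(max(d[seg2$soma_mask]), 10 + 2)  # no arm pixels in the soma
})

test_that("soma/process masks partition the cell for arbitrary inputs", {
  set.seed(5)
  for (i in 1:5) {
    ph <- make_star_astrocyte(phantom_spec(soma_radius = sample(6:14, 1),
                                           n_primaries = sample(0:6, 1),
                                           arm_length = sample(20:60, 1),
                                           jitter = 0.4, seed = i))
    seg <- separate_soma(ph$truth$mask)
    expect_identical(seg$soma_mask | seg$process_mask, seg$cell_mask)
    expect_false(any(seg$soma_mask & seg$process_mask))
    expect_true(seg$soma_mask[seg$soma_center[1], seg$soma_center[2]])
    expect_equal(max(label_components(seg$soma_mask)), 1L)
  }
})

test_that("a hint inside a thin arm falls back to the inscribed disc", {
  ph <- make_star_astrocyte(phantom_spec(soma_radius = 10, n_primaries = 4,
                                         arm_length = 60))
  ctr <- ph$truth$center
  hint <- c(ctr[1] - 40, ctr[2])  # on arm 1, 40 px out
  expect_true(ph$truth$mask[hint[1], hint[2]])
  seg <- separate_soma(ph$truth$mask, soma_center_hint = hint)
  # never a 1-px "soma": fallback produces the real soma disc
  expect_gte(sum(seg$soma_mask), 0.5 * ph$truth$soma_area)
})

test_that("field counting recovers planted counts and filters specks", {
  empty <- calibrated_image(matrix(30, 100, 100), 1)
  expect_equal(count_cells_in_field(empty), 0L)

  f <- make_field_image(7, min_separation = 60, seed = 4)
  expect_equal(count_cells_in_field(f$image), 7L)

  # planted cells + sub-threshold specks
  f5 <- make_field_image(5, min_separation = 70, seed = 6)
  px <- f5$image$pixels
  set.seed(8)
  for (i in 1:20) {  # 1-px specks, area 1 um^2 < default 20 um^2
    r <- sample(5:390, 1); c <- sample(5:390, 1)
    if (all(px[(r - 3):(r + 3), (c - 3):(c + 3)] < 100)) px[r, c] <- 200
  }
  speckled <- calibrated_image(px, f5$image$microns_per_px)
  expect_equal(count_cells_in_field(speckled), 5L)
})

test_that("field counts are invariant to translating the layout", {
  f <- make_field_image(4, min_separation = 80, seed = 9)
  m <- f$truth$mask
  shifted <- matrix(FALSE, nrow(m), ncol(m))
  shifted[11:nrow(m), 11:ncol(m)] <- m[1:(nrow(m) - 10), 1:(ncol(m) - 10)]
  expect_equal(count_cells_in_field(mask_to_image(shifted, 1)),
               count_cells_in_field(mask_to_image(m, 1)))
})

test_that("summarize_case sums fields and rejects negatives", {
  expect_equal(summarize_case(rep(3, 10))$cumulative, 30L)
  expect_equal(summarize_case(rep(0, 10))$cumulative, 0L)
  expect_equal(summarize_case(1:10)$cumulative, 55L)
  expect_error(summarize_case(c(3, -1)), "negative")
  expect_error(summarize_case(integer(0)), "nonempty")
  df <- as.data.frame(summarize_case(1:10, case_id = "c1", group = "control",
                                     compartment = "WM"))
  expect_named(df, c("case_id", "group", "compartment",
                     paste0("field_", 1:10), "cumulative"))
})
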