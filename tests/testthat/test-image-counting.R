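test_that("to_grayscale handles grayscale, RGB, and bad channel counts", {
  m <- matrix(runif(100, 0, 255), 10, 10)
  expect_identical(to_grayscale(m), m)

  black <- array(0, dim = c(6, 6, 3))
  expect_equal(to_grayscale(black), matrix(0, 6, 6))

  red <- array(0, dim = c(6, 6, 3))
  red[, , 1] <- 200
  expect_equal(to_grayscale(red), matrix(200 * 0.299, 6, 6))

  expect_error(to_grayscale(array(0, dim = c(4, 4, 2))), "channel count")
})

test_that("morphological opening removes sub-disk spots and keeps plateaus", {
  # opening is idempotent on a flat image
  flat <- matrix(50, 60, 60)
  expect_equal(estimate_background(flat, 10), flat)

  # a bright spot smaller than the disk vanishes from the background
  spot <- paste_disk(matrix(50, 80, 80), 40, 40, 5, 200)
  expect_equal(estimate_background(spot, 10), matrix(50, 80, 80))

  # a plateau larger than the disk survives
  plateau <- paste_disk(matrix(50, 90, 90), 45, 45, 30, 200)
  bg <- estimate_background(plateau, 10)
  expect_equal(bg[45, 45], 200)
  expect_equal(bg[5, 5], 50)

  # output never exceeds input
  set.seed(4)
  img <- matrix(sample(0:255, 50 * 40, replace = TRUE), 50, 40)
  expect_true(all(estimate_background(img, 3) <= img))

  expect_error(estimate_background(matrix(0, 10, 10), 6), "does not fit")
})

test_that("opening agrees with the brute-force erosion/dilation oracle", {
  set.seed(11)
  for (case in 1:12) {
    h <- sample(12:48, 1); w <- sample(12:48, 1)
    r <- sample(1:4, 1)
    img <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
    expect_equal(estimate_background(img, r), bf_opening(img, r),
                 tolerance = 1e-12)
  }
})

test_that("background subtraction and contrast enhancement behave as specified", {
  g <- matrix(runif(400, 20, 80), 20, 20)
  # flat field: image equals its background -> all zero
  expect_equal(subtract_and_enhance(g, g, 4), matrix(0, 20, 20))

  # zero background: subtraction is a no-op up to the contrast rescale
  zero <- matrix(0, 20, 20)
  enh <- subtract_and_enhance(g, zero, 3, contrast = "minmax")
  expect_equal(enh, (g - min(g)) / (max(g) - min(g)) * 255)
  # the bright-median anchor pins the upper bright population at white
  enh_bm <- subtract_and_enhance(g, zero, 1, contrast = "bright_median")
  expect_gte(mean(enh_bm >= 255 - 1e-9), 0.25)

  expect_error(subtract_and_enhance(g, matrix(0, 10, 10), 2), "dimensions")
})

test_that("binarization, size filtering, and labelling follow the rules", {
  roi <- matrix(TRUE, 100, 100)

  # degenerate (constant) image: zero components, not an error
  lab <- binarize_and_filter(matrix(0, 100, 100), roi)
  expect_identical(max(lab), 0L)

  # two well-separated spots of area ~314 px are two components
  img <- matrix(0, 100, 100)
  img <- paste_disk(img, 25, 25, 10, 200)
  img <- paste_disk(img, 75, 75, 10, 200)
  lab <- binarize_and_filter(img, roi)
  expect_identical(max(lab), 2L)
  areas <- tabulate(lab[lab > 0])
  expect_true(all(areas >= 31 & areas <= 943))

  # an artifact larger than size_max_px is removed
  big <- paste_disk(matrix(0, 100, 100), 50, 50, 40, 200)  # ~5000 px
  expect_gt(sum(big > 0), 4900)
  lab <- binarize_and_filter(big, roi, count_params(size_max_px = 1000L))
  expect_identical(max(lab), 0L)

  # labels are compact 1..n
  lab <- binarize_and_filter(img, roi)
  expect_identical(sort(unique(as.vector(lab[lab > 0]))), 1:2)

  expect_error(binarize_and_filter(img, matrix(FALSE, 100, 100)), "empty ROI")
})

test_that("connectivity 4 separates diagonal neighbours that 8 joins", {
  img <- matrix(0, 50, 50)
  # two diagonal-touching 6x6 squares
  img[10:15, 10:15] <- 200
  img[16:21, 16:21] <- 200
  roi <- matrix(TRUE, 50, 50)
  p8 <- count_params(size_min_px = 1L, size_max_px = 943L, connectivity = 8L)
  p4 <- count_params(size_min_px = 1L, size_max_px = 943L, connectivity = 4L)
  expect_identical(max(binarize_and_filter(img, roi, p8)), 1L)
  expect_identical(max(binarize_and_filter(img, roi, p4)), 2L)
})

test_that("count_cells recovers ground truth and is stable over 3-5 subtractions", {
  sim <- generate_micrograph(quick_spec(12, seed = 21))
  counts <- vapply(3:5, function(k) {
    count_cells(sim$image, sim$roi, count_params(n_subtractions = k))$n_cells
  }, integer(1))
  expect_identical(counts, rep(12L, 3))

  # blank field counts zero
  blank <- matrix(60, 120, 120)
  expect_identical(count_cells(blank, matrix(TRUE, 120, 120))$n_cells, 0L)

  # result invariants
  res <- count_cells(sim$image, sim$roi)
  expect_identical(res$n_cells, max(res$label_map))
  expect_identical(res$cell_area_px, sum(res$label_map > 0))
  expect_lte(res$cell_area_px, res$roi_area_px)
  expect_s3_class(res, "count_result")
  expect_output(print(res), "cells counted")
})

test_that("counts are invariant to a constant intensity offset", {
  sim <- generate_micrograph(quick_spec(10, seed = 31))
  shifted <- pmin(sim$image + 20, 255)
  expect_identical(count_cells(sim$image, sim$roi)$n_cells,
                   count_cells(shifted, sim$roi)$n_cells)
})

test_that("tightening the size filter never increases the count", {
  sim <- generate_micrograph(quick_spec(15, seed = 41))
  base <- count_cells(sim$image, sim$roi)$n_cells
  higher_min <- count_cells(sim$image, sim$roi,
                            count_params(size_min_px = 120L))$n_cells
  lower_max <- count_cells(sim$image, sim$roi,
                           count_params(size_max_px = 160L))$n_cells
  expect_lte(higher_min, base)
  expect_lte(lower_max, base)
})

test_that("pearson_r matches the closed form and rejects degenerate input", {
  expect_equal(pearson_r(1:5, 1:5), 1.0)
  expect_equal(pearson_r(1:5, -(1:5)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.9819805, tolerance = 1e-6)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("count_params validates its arguments", {
  expect_error(count_params(size_min_px = 900L, size_max_px = 800L), "smaller")
  expect_error(count_params(n_subtractions = 0L), ">= 1")
  expect_error(count_params(connectivity = 6L), "4 or 8")
  expect_error(count_params(threshold = "fixed"), "threshold_value")
})
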