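test_that("an empty spec renders a uniform field at the background level", {
  spec <- image_spec(width_px = 120, height_px = 120, n_cells = 0L,
                     gradient_amplitude = 0, noise_sd = 0,
                     n_small_artifacts = 0L, n_large_artifacts = 0L, seed = 1)
  sim <- generate_micrograph(spec)
  expect_true(all(sim$image == 50))
  expect_identical(sim$truth$n_cells, 0L)
  expect_identical(nrow(sim$truth$cell_centers), 0L)
})

test_that("micrograph generation is a pure function of its spec", {
  spec <- image_spec(n_cells = 20L, seed = 1)
  a <- generate_micrograph(spec)
  b <- generate_micrograph(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- generate_micrograph(image_spec(n_cells = 20L, seed = 2))
  expect_false(identical(a$image, c$image))
})

test_that("ground truth lists every cell, inside the ROI, at the required separation", {
  spec <- quick_spec(20, seed = 3)
  sim <- generate_micrograph(spec)
  ctr <- sim$truth$cell_centers
  expect_identical(nrow(ctr), 20L)
  expect_identical(sim$truth$n_cells, 20L)
  expect_true(all(sim$roi[cbind(round(ctr$y), round(ctr$x))]))
  d <- as.matrix(dist(ctr))
  diag(d) <- Inf
  expect_gte(min(d), spec$min_center_separation_px)
})

test_that("unsatisfiable placement fails with an explicit separation error", {
  spec <- image_spec(width_px = 100, height_px = 100, n_cells = 50L,
                     n_small_artifacts = 0L, n_large_artifacts = 0L, seed = 1)
  expect_error(generate_micrograph(spec), "min_center_separation_px")
})

test_that("image specs enforce the brightness invariant", {
  expect_error(image_spec(cell_peak_intensity = 60, background_level = 50,
                          gradient_amplitude = 30),
               "brighter than the local background")
})

test_that("artifact ground truth marks bright pixels off the cells", {
  sim <- generate_micrograph(image_spec(n_cells = 10L, seed = 7))
  expect_length(sim$truth$artifact_pixels, 3L)  # 2 small + 1 large by default
  sizes <- lengths(sim$truth$artifact_pixels)
  expect_true(any(sizes < 31))   # small artifacts below the size filter
  expect_true(any(sizes > 943))  # ring artifact above it
})

test_that("section series generation conserves cells at interval 1", {
  sim <- generate_section_series(800, rep(1, 40), thickness_um = 30,
                                 interval = 1L, seed = 5)
  expect_identical(sum(sim$series$records$count), sim$true_total)

  zero <- generate_section_series(0, rep(1, 40), interval = 10L, seed = 5)
  expect_identical(zero$true_total, 0L)
  expect_true(all(zero$series$records$count == 0))
})

test_that("section series generation is deterministic and validates input", {
  a <- generate_section_series(500, rep(c(0.8, 1.2), 20), interval = 10L, seed = 9)
  b <- generate_section_series(500, rep(c(0.8, 1.2), 20), interval = 10L, seed = 9)
  expect_identical(a, b)
  expect_error(generate_section_series(500, numeric(0)), "at least one")
  expect_error(generate_section_series(500, rep(1, 10), thickness_um = 0),
               "positive")
  expect_error(generate_section_series(500, rep(1, 5), interval = 10L),
               "exceeds")
})

test_that("systematic subsampling leaves the total estimator unbiased", {
  true_density <- 1000
  ests <- trues <- numeric(100)
  for (s in 1:100) {
    sim <- generate_section_series(true_density, rep(1, 100),
                                   thickness_um = 30, interval = 10L, seed = s)
    ests[s] <- estimate_total(sim$series)
    trues[s] <- sim$true_total
  }
  expect_lt(abs(mean(ests) - mean(trues)) / mean(trues), 0.05)
})

test_that("cohort generation is deterministic and validates labels", {
  d <- cohort_design(n_per_group = 3L, seed = 13)
  expect_identical(generate_cohort(d), generate_cohort(d))

  bad_sex <- default_calibration()
  bad_sex$sex[1] <- "other"
  expect_error(cohort_design(calibration = bad_sex), "male, female")

  bad_time <- default_calibration()
  bad_time$time_point[1] <- "4w"
  expect_error(cohort_design(calibration = bad_time), "2h, 24h, 1w, 2w, 3w")

  bad_mix <- default_calibration()
  bad_mix$dcx_pA[1] <- bad_mix$dcx_pA[1] + 0.05
  expect_error(cohort_design(calibration = bad_mix), "sum to 1")
})

test_that("a null design yields near-zero sex contrasts", {
  cal <- default_calibration()
  cal$brdu_density <- 8000
  cohort <- generate_cohort(cohort_design(n_per_group = 60L, calibration = cal,
                                          seed = 17))
  d <- sex_contrasts(cohort, "brdu_density")
  expect_true(all(abs(d$cohens_d) < 0.5))
})

test_that("group means recover the design truth at large n (3 SEM)", {
  cohort <- generate_cohort(cohort_design(n_per_group = 200L, seed = 19))
  cal <- default_calibration()
  summ <- summarize_trajectory(cohort, "brdu_density")
  for (sex in c("male", "female")) {
    row <- summ[summ$sex == sex & summ$region == "dorsal" &
                  summ$time_point == "1w", ]
    truth <- cal$brdu_density[cal$sex == sex & cal$region == "dorsal" &
                                cal$time_point == "1w"]
    expect_lt(abs(row$mean - truth), 3 * row$sem)
  }
  # NeuN percentage at 3w recovers the ~90% design truth
  s90 <- summarize_trajectory(cohort, "pct_neun")
  for (sex in c("male", "female")) {
    row <- s90[s90$sex == sex & s90$region == "dorsal" & s90$time_point == "3w", ]
    expect_lt(abs(row$mean - 90), 3 * row$sem)
  }
})

test_that("a designed 1w to 2w halving propagates to the attrition estimate", {
  cohort <- generate_cohort(cohort_design(n_per_group = 120L, seed = 23))
  summ <- summarize_trajectory(cohort, "brdu_density")
  att <- attrition(summ, "male", "dorsal", "1w", "2w")
  expect_lt(abs(att - (-50)), 8)
})
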