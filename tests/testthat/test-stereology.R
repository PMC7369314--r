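test_that("bregma coordinates map to dorsal, ventral, or out of range", {
  expect_identical(classify_region(-3.8), "dorsal")
  expect_identical(classify_region(-6.8), "ventral")
  expect_identical(classify_region(-1.0), "out_of_range")
  # shared boundary belongs to ventral; dorsal interval is half-open
  expect_identical(classify_region(-4.52), "ventral")
  expect_identical(classify_region(-1.80), "dorsal")
  expect_identical(classify_region(-6.81), "out_of_range")
  expect_error(classify_region(NA_real_), "finite")
})

test_that("region classification partitions the coordinate range", {
  grid <- seq(-6.80, -1.80, by = 0.004)
  reg <- classify_region(grid)
  expect_true(all(reg %in% c("dorsal", "ventral")))
  # monotone: ventral strictly caudal to dorsal
  expect_true(max(grid[reg == "ventral"]) < min(grid[reg == "dorsal"]))
})

test_that("total estimate is aggregate times sampling interval", {
  s <- section_series(data.frame(bregma_mm = c(-2, -2.3, -2.6),
                                 area_mm2 = c(1, 1, 1), count = c(3L, 5L, 2L)))
  expect_equal(estimate_total(s), 100)
  s0 <- section_series(data.frame(bregma_mm = c(-2, -2.3),
                                  area_mm2 = c(1, 1), count = c(0L, 0L)))
  expect_equal(estimate_total(s0), 0)
  # linear in counts
  s2 <- section_series(data.frame(bregma_mm = c(-2, -2.3, -2.6),
                                  area_mm2 = c(1, 1, 1), count = c(6L, 10L, 4L)))
  expect_equal(estimate_total(s2), 2 * estimate_total(s))
})

test_that("Cavalieri volume uses the effective section spacing", {
  # two 1-mm^2 sections, 30-um sections, 1-in-10 series: 300-um spacing
  s <- section_series(data.frame(bregma_mm = c(-2, -2.3),
                                 area_mm2 = c(1, 1), count = c(0L, 0L)),
                      sampling_interval = 10L, section_thickness_um = 30)
  expect_equal(cavalieri_volume(s), 0.6)
  # linear in areas
  s2 <- section_series(data.frame(bregma_mm = c(-2, -2.3),
                                  area_mm2 = c(2, 2), count = c(0L, 0L)))
  expect_equal(cavalieri_volume(s2), 2 * cavalieri_volume(s))
})

test_that("a sub-sampled constant-area prism recovers its volume within one slab", {
  areas <- rep(1, 95)
  bregma <- -1.8 - (seq_along(areas) - 1) * 0.03
  full <- section_series(data.frame(bregma_mm = bregma, area_mm2 = areas,
                                    count = 0L),
                         sampling_interval = 1L, section_thickness_um = 30)
  keep <- seq(1, 95, by = 10)
  sub <- section_series(data.frame(bregma_mm = bregma[keep],
                                   area_mm2 = areas[keep], count = 0L),
                        sampling_interval = 10L, section_thickness_um = 30)
  expect_lte(abs(cavalieri_volume(sub) - cavalieri_volume(full)), 0.3)
})

test_that("density ties the total and the volume together", {
  s <- section_series(data.frame(bregma_mm = -2, area_mm2 = 1, count = 10L),
                      sampling_interval = 10L, section_thickness_um = 50)
  est <- cell_density(s)
  expect_equal(est$volume_mm3, 0.5)
  expect_equal(est$est_total_cells, 100)
  expect_equal(est$density_cells_per_mm3, 200)
  expect_equal(est$density_cells_per_mm3 * est$volume_mm3, est$est_total_cells)

  szero <- section_series(data.frame(bregma_mm = -2, area_mm2 = 1, count = 0L))
  expect_equal(cell_density(szero)$density_cells_per_mm3, 0)

  sbad <- section_series(data.frame(bregma_mm = -2, area_mm2 = 0, count = 3L))
  expect_error(cell_density(sbad), "areas are zero")
})

test_that("density estimates recover the generating density", {
  devs <- numeric(60)
  for (s in 1:60) {
    sim <- generate_section_series(1000, rep(1, 100), thickness_um = 30,
                                   interval = 10L, seed = 200 + s)
    est <- cell_density(sim$series)
    devs[s] <- est$density_cells_per_mm3
  }
  expect_lt(abs(mean(devs) - 1000) / 1000, 0.05)
})

test_that("series split by region and section tables round-trip through CSV", {
  df <- data.frame(bregma_mm = c(-2.0, -3.0, -5.0, -6.0),
                   area_mm2 = c(1, 1, 2, 2), count = c(5L, 5L, 8L, 2L))
  s <- section_series(df, sampling_interval = 10L, section_thickness_um = 30)
  by_reg <- density_by_region(s)
  expect_named(by_reg, c("dorsal", "ventral"))
  expect_equal(by_reg$dorsal$est_total_cells, 100)
  expect_equal(by_reg$ventral$volume_mm3, 1.2)

  path <- tempfile(fileext = ".csv")
  write_section_table(s, path, animal_id = "rat_07")
  back <- read_section_table(path)
  expect_equal(back$bregma_mm, s$records$bregma_mm)
  expect_equal(back$count, s$records$count)
  expect_true(all(back$animal_id == "rat_07"))
})

test_that("series constructor validates records", {
  expect_error(section_series(data.frame(bregma_mm = -2, area_mm2 = -1,
                                         count = 0L)), ">= 0")
  expect_error(section_series(data.frame(bregma_mm = -2, area_mm2 = 1,
                                         count = 2.5)), "integers")
  expect_error(section_series(data.frame(a = 1)), "columns")
  expect_error(section_series(data.frame(bregma_mm = numeric(0),
                                         area_mm2 = numeric(0),
                                         count = integer(0))), "at least one")
})
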