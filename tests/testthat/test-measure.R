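# Lumen-area measurement (free-boundary trace vs rasterization oracle),
# apical/basal morphometry and ensemble statistics.

test_that("confluent tissue has no measurable lumen", {
  st <- relaxed_pair(relax_s = 300)
  rec <- measure_lumen(st)
  expect_equal(rec$area, 0)
})

test_that("a scripted annular cavity measures its exact area", {
  st <- annulus_fixture(r_in = 10)
  rec <- measure_lumen(st)
  expect_gt(rec$area, 0)
  expect_lt(abs(rec$area - pi * 100) / (pi * 100), 0.02)
  expect_equal(rec$n_cholangiocytes_lining, 6L)
  # rasterization oracle agrees
  ras <- raster_cavity_area(st, rec$polygon, h = 0.1)
  expect_lt(abs(ras - rec$area) / rec$area, 0.02)
})

test_that("the trace agrees with the rasterization oracle on simulation
          snapshots", {
  cfg <- fast_cfg()
  os <- run_bilayer("osmosis", cfg, seed = 1, duration = 1.5)
  rec <- measure_lumen(os)
  if (rec$area > 20) {
    ras <- raster_cavity_area(os, rec$polygon, h = 0.1)
    expect_lt(abs(ras - rec$area) / rec$area, 0.02)
  } else {
    succeed("no sizeable cavity at this snapshot")
  }
})

test_that("apical/basal arc lengths behave under symmetry and scaling", {
  cfg <- fast_cfg()
  cl <- build_cell(c(0, 0), 10, 72, "cholangiocyte", cfg)
  cl$polarity <- polarity_state(c(0, 1))
  cl <- classify_regions(cl)
  m <- measure_apical_basal(cl)
  expect_equal(m$ratio, 1, tolerance = 2 / 72 + 1e-9)
  cl2 <- cl
  cl2$xy <- cl$xy * 2
  m2 <- measure_apical_basal(cl2)
  expect_equal(m2$apical, 2 * m$apical, tolerance = 1e-9)
  expect_equal(m2$ratio, m$ratio, tolerance = 1e-9)
  # unpolarized cells are flagged
  cl$polarity <- NULL
  expect_false(measure_apical_basal(cl)$polarized)
})

test_that("ensemble statistics combine runs pointwise", {
  r1 <- data.frame(time = 0:4, area = c(0, 1, 2, 3, 4))
  r2 <- data.frame(time = 0:4, area = c(0, 1, 2, 3, 4))
  es <- ensemble_stats(list(r1, r2))
  expect_equal(es$sd, rep(0, 5))
  expect_equal(es$lo, es$mean)
  r3 <- data.frame(time = 0, area = 0)
  r4 <- data.frame(time = 0, area = 2)
  es2 <- ensemble_stats(list(r3, r4))
  expect_equal(es2$mean, 1)
  expect_equal(es2$lo, 0)          # clipped at zero for areas
  expect_equal(es2$hi, 1 + 2 * sd(c(0, 2)))
  expect_equal(es2$min, 0)
  expect_equal(es2$max, 2)
  expect_warning(ensemble_stats(list(r1, data.frame(time = c(0, 4),
                                                    area = c(0, 4)))),
                 "resampling")
})
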