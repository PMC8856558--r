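# Center-based model: JKR closed forms, Langevin stepping, hybrid
# DCM-CBM coupling and the pair-level calibration claims.

test_that("the contact law reduces to Hertz at W = 0", {
  Es <- 1 / (2 * (1 - 0.47^2) / lumensim:::pa2int(450))
  Rs <- 5
  del <- c(0.01, 0.05, 0.1)
  F <- jkr_force(del, 10, 10, W = 0)
  hertz <- (4 / 3) * Es * sqrt(Rs) * del^1.5
  expect_lt(max(abs(F - hertz) / hertz), 1e-6)
  expect_equal(jkr_force(-0.5, 10, 10, W = 0), 0)
})

test_that("the pull-off force is (3/2) pi W R*", {
  Rs <- 5
  w <- 9e-4 * 1000
  dd <- seq(-4, 0.2, length.out = 40000)
  F <- jkr_force(dd, 10, 10, W = 9e-4)
  expect_equal(-min(F), 1.5 * pi * w * Rs, tolerance = 1e-6)
  # beyond the detachment separation the force vanishes
  expect_equal(jkr_force(-10, 10, 10, W = 9e-4), 0)
})

test_that("CBM stepping is symmetric, keeps fixed cells immobile, and
          reproduces the motility", {
  cfg <- fast_cfg()
  st <- mech_state(cfg = cfg, seed = 1)
  st <- add_cbm_cells(st, c(-4.5, 4.5), c(0, 0), c(5, 5), "hepatoblast",
                      quiescent = TRUE, age = c(0, 0))
  st$cbm$D <- 0
  st2 <- advance_mechanics(st, 20, dt = 0.5)
  dx <- st2$cbm$x - st$cbm$x
  expect_equal(dx[1], -dx[2], tolerance = 1e-9)
  expect_gt(abs(dx[1]), 1e-4)  # repulsive overlap resolves
  # no forces, no noise: no motion
  st3 <- mech_state(cfg = cfg, seed = 1)
  st3 <- add_cbm_cells(st3, c(0, 30), c(0, 0), c(5, 5), "hepatoblast",
                       quiescent = TRUE, age = c(0, 0))
  st3$cbm$D <- 0
  st4 <- advance_mechanics(st3, 20, dt = 0.5)
  expect_equal(st4$cbm$x, st3$cbm$x, tolerance = 1e-12)
  # fixed cells never move
  st5 <- mech_state(cfg = fast_cfg(), seed = 2)
  st5 <- add_cbm_cells(st5, c(0, 8), c(0, 0), c(5, 5), "endothelium",
                       fixed = TRUE)
  st6 <- advance_mechanics(st5, 50, dt = 0.5)
  expect_equal(st6$cbm$x, st5$cbm$x)
  # free-cell MSD slope = 4D
  msd <- numeric(200)
  tt <- 2000
  for (r in 1:200) {
    s1 <- mech_state(cfg = cfg, seed = r + 10)
    s1 <- add_cbm_cells(s1, 0, 0, 7.5, "hepatoblast", quiescent = TRUE,
                        age = 0)
    s1$cbm$D <- 1e-16
    s1 <- advance_mechanics(s1, tt, dt = 2)
    msd[r] <- s1$cbm$x^2 + s1$cbm$y^2
  }
  expect_equal(mean(msd) / tt, 4 * 1e-16 * 1e12, tolerance = 0.15)
})

test_that("hybrid DCM-CBM contact is mechanically consistent", {
  cfg <- fast_cfg()
  cl <- build_cell(c(0, 0), 10, 36, "hepatoblast", cfg)
  cl$id <- 1L; cl$D <- 0
  st <- mech_state(list(cl), cfg = cfg)
  st <- add_cbm_cells(st, 14.8, 0, 5, "endothelium", fixed = TRUE)
  out <- hybrid_contact_forces(st)
  expect_gt(max(abs(out$F)), 0)
  expect_lt(max(abs(colSums(out$F) + out$Fcbm[1, ])), 1e-10)
  # pressing deforms the cell, the fixed center does not move
  st2 <- advance_mechanics(st, 300)
  expect_equal(st2$cbm$x, st$cbm$x)
  expect_false(isTRUE(all.equal(st2$cells[[1]]$xy, cl$xy)))
  # far apart: zero coupling
  st$cbm$x <- 100
  out2 <- hybrid_contact_forces(st)
  expect_equal(max(abs(out2$F)), 0)
})

test_that("a calibrated CBM pair matches the DCM pair response", {
  # Both probes use the calibration protocol (relaxation short against the
  # cortical turnover time): the DCM pair response is elastic there, and
  # the calibrated sphere law must reproduce it.
  cfg <- fast_cfg()
  set.seed(31)
  # DCM force-free spacing under the calibration protocol
  a <- build_cell(c(-9, 0), 10, 36, "hepatoblast", cfg, id = 1L)
  b <- build_cell(c(9, 0), 10, 36, "hepatoblast", cfg, id = 2L)
  a$D <- 0; b$D <- 0
  std <- mech_state(list(a, b), cfg = cfg)
  std <- advance_mechanics(std, 240)
  d_dcm <- sqrt(sum((lumensim:::polygon_centroid(std$cells[[1]]$xy) -
                     lumensim:::polygon_centroid(std$cells[[2]]$xy))^2))
  Rsum <- lumensim:::cell_radius_eff(std$cells[[1]]) +
    lumensim:::cell_radius_eff(std$cells[[2]])
  # CBM pair with identical W and elastic constants relaxes to its static
  # equilibrium spacing
  stc <- mech_state(cfg = cfg, seed = 3)
  stc <- add_cbm_cells(stc, c(-9, 9), c(0, 0), c(10, 10), "hepatoblast",
                       quiescent = TRUE, age = c(0, 0))
  stc$cbm$D <- 0
  stc <- advance_mechanics(stc, 4000, dt = 2)
  d_cbm <- abs(diff(stc$cbm$x))
  expect_lt(abs(d_cbm - d_dcm) / d_dcm, 0.10)

  # force-overlap response: the calibrated law reproduces the measured
  # DCM pair compression curve within 20%
  set.seed(32)
  forces <- c(0, 2, 5, 10, 20)
  tab <- calibrate_cbm_contact(cfg, forces = forces, relax_s = 240)
  for (k in 3:length(tab$x)) {
    del <- tab$x[k] * 5
    Fpred <- jkr_force(del, 10, 10, W = cfg$dcm$W, mult = tab)
    Fapplied <- forces[k - 1]
    expect_lt(abs(Fpred - Fapplied) / max(Fapplied, 5), 0.2)
  }
})
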