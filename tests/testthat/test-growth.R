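# Growth ramp, five-stage division, proliferation-rate controller and
# differentiation.

test_that("the reference volume ramps linearly and quiescent cells freeze", {
  cl <- build_cell(c(0, 0), 10, 36, "hepatoblast")
  cl$tau <- 24
  cl2 <- grow(cl, 12)
  expect_equal(cl2$Aref, 1.5 * cl2$birthA)
  cl$quiescent <- TRUE
  expect_equal(grow(cl, 10)$Aref, cl$Aref)
})

test_that("random division axes are uniform on [0, pi)", {
  set.seed(12)
  ang <- replicate(10000, {
    v <- division_axis(NULL, "random")
    atan2(v[2], v[1]) %% pi
  })
  expect_gt(stats::ks.test(ang, "punif", 0, pi)$p.value, 0.01)
})

test_that("oriented division separates daughters along the planar
          polarity and conserves volume", {
  cfg <- fast_cfg()
  set.seed(2)
  m <- build_cell(c(0, 0), 10, 36, "cholangiocyte", cfg)
  m$id <- 1L
  m$D <- 0
  m$polarity <- polarity_state(c(0, 1), pcp = c(1, 0))
  m$Aref <- 2 * m$birthA
  st <- mech_state(list(m), cfg = cfg)
  st <- divide_cell(st, 1, "along_pcp")
  expect_length(st$cells, 2)
  A1 <- lumensim:::polygon_area(st$cells[[1]]$xy)
  A2 <- lumensim:::polygon_area(st$cells[[2]]$xy)
  # at division the rounded-up mother carries its doubled volume; the two
  # daughters together conserve it
  expect_lt(abs(A1 + A2 - 2 * m$birthA) / (2 * m$birthA), 0.05)
  c1 <- lumensim:::polygon_centroid(st$cells[[1]]$xy)
  c2 <- lumensim:::polygon_centroid(st$cells[[2]]$xy)
  sep <- c2 - c1
  ang <- atan2(abs(sep[2]), abs(sep[1]))
  expect_lt(ang, 10 * pi / 180)
  # daughters inherit type and polarity
  expect_equal(st$cells[[2]]$type, "cholangiocyte")
  expect_equal(st$cells[[2]]$polarity$pcp, m$polarity$pcp)
  # resolution guard
  tiny <- build_cell(c(50, 0), 10, 20, "hepatoblast", cfg)
  tiny$id <- 5L
  st2 <- mech_state(list(tiny), cfg = cfg)
  expect_error(divide_cell(st2, 1), "24 nodes")
})

test_that("the controller drives cycling counts to the set-point", {
  cfg <- fast_cfg()
  set.seed(4)
  cells <- lapply(1:100, function(i) {
    cl <- build_cell(c(30 * (i %% 10), 30 * (i %/% 10)), 5, 12,
                     "cholangiocyte", cfg, id = i)
    cl
  })
  st <- mech_state(cells, cfg = cfg)
  # an integer target is met exactly at every invocation
  for (k in 1:5) {
    st <- proliferation_controller(st, c(cholangiocyte = 0.26))
    cyc <- sum(!vapply(st$cells, `[[`, TRUE, "quiescent"))
    expect_equal(cyc, 26)
  }
  # target 0: everything quiescent; target 1: nothing forced quiescent
  st <- proliferation_controller(st, c(cholangiocyte = 0))
  expect_true(all(vapply(st$cells, `[[`, TRUE, "quiescent")))
  st <- proliferation_controller(st, c(cholangiocyte = 1))
  expect_true(!any(vapply(st$cells, `[[`, TRUE, "quiescent")))
  # fractional targets are met within one cell at every step
  for (k in 1:10) {
    st <- proliferation_controller(st, c(cholangiocyte = 0.107))
    cyc <- sum(!vapply(st$cells, `[[`, TRUE, "quiescent"))
    expect_lt(abs(cyc - 10.7), 1)
  }
})

test_that("differentiation requires cholangiocyte contact plus lumen
          adjacency, runs on the signalling clock, and shrinks the cell", {
  cfg <- fast_cfg()
  set.seed(6)
  # hepatoblast without a cholangiocyte neighbour: timer frozen
  a <- build_cell(c(-9.6, 0), 10, 36, "hepatoblast", cfg)
  b <- build_cell(c(9.6, 0), 10, 36, "hepatoblast", cfg)
  a$id <- 1L; b$id <- 2L; a$D <- 0; b$D <- 0
  st <- mech_state(list(a, b), cfg = cfg)
  st <- differentiate_cells(st, dt = 1, T_sig = 2)
  expect_true(all(is.na(vapply(st$cells, `[[`, 1, "sig_timer"))))
  # with a cholangiocyte neighbour and free space, conversion at T_sig
  st$cells[[2]]$type <- "cholangiocyte"
  t_conv <- NA
  for (k in 1:30) {
    st <- differentiate_cells(st, dt = 0.25, T_sig = 2)
    if (st$cells[[1]]$type == "cholangiocyte") { t_conv <- k * 0.25; break }
  }
  expect_false(is.na(t_conv))
  expect_lt(abs(t_conv - 2), 0.3)
  # conversion scales the reference volume by 0.75
  expect_equal(st$cells[[1]]$birthA, 0.75 * a$birthA, tolerance = 1e-9)
  expect_true(st$cells[[1]]$secreting)
  expect_false(is.null(st$cells[[1]]$polarity))
})
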