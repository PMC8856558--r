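# Tracer-particle secretion, diffusion with membrane rules, and
# osmotic surface marking.

test_that("secretion is Poisson at the configured rate and gated by type", {
  cfg <- fast_cfg()
  cl <- build_cell(c(0, 0), 8, 36, "cholangiocyte", cfg)
  cl$id <- 1L
  cl$secreting <- TRUE
  st0 <- mech_state(list(cl), cfg = cfg)
  set.seed(5)
  counts <- replicate(1000, {
    st <- secrete(st0, dt = 1, rate = 10)
    nrow(st$particles)
  })
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 1000))
  # rate 0 and non-cholangiocytes produce nothing
  expect_equal(nrow(secrete(st0, 1, rate = 0)$particles), 0)
  st0$cells[[1]]$type <- "hepatoblast"
  expect_equal(nrow(secrete(st0, 1)$particles), 0)
})

test_that("free-space random walk has MSD slope 4 D_tp", {
  cfg <- fast_cfg()
  st <- mech_state(cfg = cfg, seed = 9)
  st$particles <- data.frame(id = 1:100, x = 0, y = 0, owner = 0L,
                             origin = 0L)
  secs <- 100
  st2 <- diffuse_and_transfer(st, secs, nsteps = 1000L)
  msd <- mean(st2$particles$x^2 + st2$particles$y^2)
  D <- lumensim:::d2int(cfg$tracer$D_tp)
  expect_equal(msd / secs, 4 * D, tolerance = 0.15)
  # D_tp = 0: no motion
  cfg0 <- cfg; cfg0$tracer$D_tp <- 0
  st$config <- cfg0
  st3 <- diffuse_and_transfer(st, secs, nsteps = 10L)
  expect_equal(st3$particles$x, rep(0, 100))
})

test_that("particles stay inside a fully contacted cell but exit through
          free apical surface", {
  cfg <- fast_cfg()
  # enclosed: a cell tightly ringed by neighbours on all sides
  st <- relaxed_pair(cfg, relax_s = 400)
  st$cells[[1]]$polarity <- polarity_state(c(1, 0))  # apical at the contact
  st$cells[[1]] <- classify_regions(st$cells[[1]])
  # put the apical cone into the contact zone: particles cannot leave there
  st <- lumensim:::seed_secretion(st, 1L, 30L)
  st2 <- diffuse_and_transfer(st, 300, nsteps = 200L)
  inside1 <- st2$particles$owner == 1L
  # exits require open apical surface; the contact side is sealed, and the
  # free side is not apical, so most particles stay inside (absorption of
  # swept particles aside, none may sit in a foreign cell)
  for (k in which(st2$particles$owner == 0L)) {
    p <- as.matrix(st2$particles[k, c("x", "y")])
    expect_false(any(vapply(st2$cells, function(cl)
      as.logical(lumensim:::cpp_points_in_ring(p, cl$xy)), TRUE)))
  }
  # open apical surface: exits happen (toy cell alone in the medium)
  cl <- build_cell(c(0, 0), 8, 36, "cholangiocyte", cfg)
  cl$id <- 1L
  cl$polarity <- polarity_state(c(1, 0))
  cl <- classify_regions(cl)
  sto <- mech_state(list(cl), cfg = cfg)
  sto <- lumensim:::seed_secretion(sto, 1L, 20L)
  sto2 <- diffuse_and_transfer(sto, 60, nsteps = 40L)
  expect_gt(sum(sto2$particles$owner == 0L), 5)
  # and the escaped particles mark open surface elements
  sto3 <- mark_surfaces(sto2)
  expect_gt(sum(sto3$cells[[1]]$marked), 0)
})

test_that("particle count is conserved apart from explicit secretion", {
  cfg <- fast_cfg()
  cl <- build_cell(c(0, 0), 8, 36, "cholangiocyte", cfg)
  cl$id <- 1L
  cl$polarity <- polarity_state(c(1, 0))
  cl <- classify_regions(cl)
  st <- mech_state(list(cl), cfg = cfg)
  st <- lumensim:::seed_secretion(st, 1L, 25L)
  st2 <- diffuse_and_transfer(st, 120, nsteps = 80L)
  expect_equal(nrow(st2$particles), 25)
})

test_that("marks appear on both walls of a narrow cavity and clear when
          the walls seal", {
  cfg <- fast_cfg()
  st <- flat_plate_pair(L = 16, gap = 0.6, cfg = cfg)
  st$particles <- data.frame(id = 1:5, x = 0, y = 0.05, owner = 0L,
                             origin = 0L)
  st <- mark_surfaces(st)
  m1 <- sum(st$cells[[1]]$marked)
  m2 <- sum(st$cells[[2]]$marked)
  expect_gt(m1, 0)
  expect_gt(m2, 0)
  # press the plates together: sustained closure clears the marks
  st$particles <- st$particles[0, ]
  st$cells[[1]]$xy[, 2] <- st$cells[[1]]$xy[, 2] - 0.58
  st <- mark_surfaces(st)
  expect_equal(sum(st$cells[[1]]$marked) + sum(st$cells[[2]]$marked), 0)
})

test_that("osmotic loading is zero without pressure and balances on a
          closed marked ring", {
  cfg <- fast_cfg()
  cl <- build_cell(c(0, 0), 10, 36, "hepatoblast", cfg)
  cl$marked <- rep(1L, 36)
  st <- mech_state(list(cl), cfg = cfg)
  expect_equal(max(abs(osmotic_forces(st, 0))), 0)
  F <- osmotic_forces(st, 50)
  expect_gt(max(abs(F)), 0)
  expect_lt(max(abs(colSums(F))), 1e-10)
})
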