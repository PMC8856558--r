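# Deformable-cell mechanics: discretization, force terms as energy
# gradients, conservation identities, and the overdamped stepper.

test_that("cell construction gives a regular ring with consistent volume", {
  cl <- build_cell(c(0, 0), 10, 60, "hepatoblast")
  expect_equal(nrow(cl$xy), 60)
  expect_lt(abs(cl$Aref - pi * 100) / (pi * 100), 0.005)
  expect_equal(cl$rest, lumensim:::edge_lengths(cl$xy), tolerance = 1e-12)
  # minimum observed hepatoblast radius is a valid cell
  expect_s3_class(build_cell(c(0, 0), 8.8, 36, "hepatoblast"), "dcm_cell")
  expect_error(build_cell(c(0, 0), 10, 6, "hepatoblast"), "12 nodes")
  expect_error(build_cell(c(0, 0), 2, 36, "hepatoblast"), "radius")
})

test_that("internal force terms vanish on the freshly built ring", {
  cfg <- fast_cfg()
  cl <- build_cell(c(0, 0), 10, 36, "hepatoblast", cfg)
  expect_lt(max(abs(inplane_forces(cl, cfg))), 1e-10)
  expect_lt(max(abs(bending_forces(cl, cfg))), 1e-10)
  expect_lt(max(abs(volume_force(cl, cfg))), 1e-10)
})

test_that("uniform dilation gives symmetric restoring in-plane forces", {
  cfg <- fast_cfg()
  cl <- build_cell(c(0, 0), 10, 36, "hepatoblast", cfg)
  cl$xy <- cl$xy * 1.1
  F <- inplane_forces(cl, cfg)
  mags <- sqrt(rowSums(F^2))
  expect_lt(diff(range(mags)) / mean(mags), 1e-9)
  inward <- rowSums(F * cl$xy) < 0
  expect_true(all(inward))
})

test_that("a node displaced outward feels a restoring bending force", {
  cfg <- fast_cfg()
  cl <- build_cell(c(0, 0), 10, 36, "hepatoblast", cfg)
  cl$xy[5, ] <- cl$xy[5, ] * 1.05
  Fb <- bending_forces(cl, cfg)
  expect_lt(sum(Fb[5, ] * cl$xy[5, ]), 0)
})

test_that("volume force implements p = K_V (1 - A/A_ref) with zero sum", {
  cfg <- fast_cfg()
  cfg$dcm$K_V <- 750
  cl <- build_cell(c(0, 0), 10, 36, "hepatoblast", cfg)
  cl$xy <- cl$xy * sqrt(0.9)   # A = 0.9 A_ref
  F <- volume_force(cl, cfg)
  # outward load of 75 Pa x element length, lumped on the two nodes
  L <- lumensim:::edge_lengths(cl$xy)
  p_exp <- lumensim:::p_line(75, cfg$dcm$h_z)   # nN per um boundary
  nodeF <- sqrt(rowSums(F^2))
  expect_equal(mean(nodeF), p_exp * mean(L), tolerance = 0.02)
  expect_lt(max(abs(colSums(F))), 1e-10)
  cl$xy <- cl$xy * 2  # any closed ring under any p
  expect_lt(max(abs(colSums(volume_force(cl, cfg)))),
            1e-10 * max(abs(volume_force(cl, cfg))))
})

test_that("every conservative force term is the negative energy gradient", {
  cfg <- fast_cfg()
  set.seed(42)
  # single-cell terms on a minimal ring
  mini <- function() {
    cl <- build_cell(c(0, 0), 5, 12, "hepatoblast", cfg)
    cl$xy <- cl$xy + matrix(rnorm(24, 0, 0.15), ncol = 2)
    lumensim:::single_state(cl, cfg)
  }
  for (term in c("inplane", "bending", "volume")) {
    worst <- 0
    for (r in 1:100) {
      st <- mini()
      F <- lumensim:::forces_raw(st, lumensim:::force_mask[term])$F
      g <- fd_gradient(st, term)
      worst <- max(worst, max(abs(F - g)) / max(max(abs(F)), 1e-8))
    }
    expect_lt(worst, 1e-6)
  }
  # contact on a touching pair with mixed surface regions; the osmotic
  # potential is defined for closed marked loops, so that term is probed
  # on a fully marked ring
  for (term in c("contact", "osmotic")) {
    worst <- 0
    for (r in 1:100) {
      a <- build_cell(c(-4.9, 0), 5, 12, "cholangiocyte", cfg, id = 1L)
      b <- build_cell(c(4.9, 0), 5, 12, "hepatoblast", cfg, id = 2L)
      a$polarity <- polarity_state(c(1, 0))
      a <- classify_regions(a)
      if (term == "osmotic") {
        a$marked <- rep(1L, 12)
        b$marked <- rep(1L, 12)
      }
      st <- mech_state(list(a, b), cfg = cfg)
      st$P_L <- 50
      for (ci in 1:2) {
        st$cells[[ci]]$xy <- st$cells[[ci]]$xy +
          matrix(rnorm(24, 0, 0.05), ncol = 2)
      }
      F <- lumensim:::forces_raw(st, lumensim:::force_mask[term])$F
      g <- fd_gradient(st, term)
      worst <- max(worst, max(abs(F - g)) / max(max(abs(F)), 1e-8))
    }
    expect_lt(worst, 1e-6)
  }
})

test_that("internal forces of an isolated cell sum to zero", {
  cfg <- fast_cfg()
  set.seed(7)
  cl <- build_cell(c(0, 0), 10, 36, "hepatoblast", cfg)
  cl$xy <- cl$xy + matrix(rnorm(72, 0, 0.4), ncol = 2)
  Fsum <- colSums(inplane_forces(cl, cfg)) +
    colSums(bending_forces(cl, cfg)) + colSums(volume_force(cl, cfg))
  rms <- sqrt(mean(inplane_forces(cl, cfg)^2))
  expect_lt(max(abs(Fsum)), 1e-9 * max(rms, 1))
})

test_that("contact forces obey action-reaction exactly", {
  st <- relaxed_pair(relax_s = 300)
  cf <- contact_forces(st$cells[[1]], st$cells[[2]], st$config)
  expect_lt(max(abs(colSums(cf$Fa) + colSums(cf$Fb))), 1e-10)
  # far apart: zero
  far <- build_cell(c(100, 0), 10, 36, "hepatoblast", st$config)
  cf2 <- contact_forces(st$cells[[1]], far, st$config)
  expect_equal(max(abs(cf2$Fa)), 0)
})

test_that("work of separating two flat adhering plates equals the
          adhesion energy per unit contact length", {
  cfg <- fast_cfg()
  # separation work is calibrated from the nominal contact plane (d = 0)
  st <- flat_plate_pair(L = 24, gap = 1e-4, cfg = cfg)
  n1 <- nrow(st$cells[[1]]$xy)
  Lpatch <- 24
  h <- 0.002
  W_num <- 0
  for (s in seq(0, 0.6, by = h)) {
    st2 <- st
    st2$cells[[1]]$xy[, 2] <- st$cells[[1]]$xy[, 2] + s
    F <- lumensim:::forces_raw(st2, 8L)$F
    W_num <- W_num + sum(F[seq_len(n1), 2]) * h
  }
  E_pair <- lumensim:::w_line(cfg$dcm$W, cfg$dcm$h_z)
  expect_equal(-W_num / Lpatch, E_pair, tolerance = 0.05)
})

test_that("a free cell under constant body force moves at F/(total drag)", {
  cfg <- fast_cfg()
  cl <- build_cell(c(0, 0), 10, 36, "hepatoblast", cfg)
  cl$D <- 0
  cl$fext <- c(3, 0)
  st <- mech_state(list(cl), cfg = cfg)
  dt <- 0.01
  st2 <- step(st, dt)
  g <- lumensim:::gamma2int(max(cfg$dcm$gamma_ECM, cfg$dcm$gamma_liq),
                            cfg$dcm$h_z) +
    lumensim:::gamma2int(cfg$dcm$gamma_int, cfg$dcm$h_z)
  n <- 36
  l0n <- cl$rest  # regular ring: all equal
  Gtot <- sum(g * l0n)
  dx <- mean(st2$cells[[1]]$xy[, 1] - cl$xy[, 1])
  expect_equal(dx, 3 / Gtot * dt, tolerance = 1e-6)
})

test_that("zero force leaves positions unchanged", {
  cfg <- fast_cfg()
  cl <- build_cell(c(0, 0), 10, 36, "hepatoblast", cfg)
  cl$D <- 0
  st <- mech_state(list(cl), cfg = cfg)
  st2 <- step(st, 0.05)
  expect_equal(st2$cells[[1]]$xy, cl$xy, tolerance = 1e-12)
})

test_that("noise-free relaxation descends the mechanical energy", {
  cfg <- fast_cfg()
  cfg$dcm$tau_ve <- 1e12   # probe the conservative core
  set.seed(11)
  cl <- build_cell(c(0, 0), 10, 36, "hepatoblast", cfg)
  cl$xy <- cl$xy + matrix(rnorm(72, 0, 0.5), ncol = 2)
  cl$D <- 0
  st <- mech_state(list(cl), cfg = cfg)
  E <- dcm_energy(st, "total")
  for (k in 1:100) {
    st <- step(st, 0.02)
    E2 <- dcm_energy(st, "total")
    expect_lte(E2, E + 1e-9)
    E <- E2
  }
})

test_that("migration force is unbiased and gives centroid diffusion 4D", {
  cfg <- fast_cfg()
  cl <- build_cell(c(0, 0), 10, 36, "hepatoblast", cfg)
  set.seed(3)
  draws <- t(replicate(2000, migration_force(cl, 1e-16, 0.05, cfg)[1, ]))
  se <- apply(draws, 2, sd) / sqrt(nrow(draws))
  expect_lt(abs(mean(draws[, 1])), 3 * se[1])
  expect_lt(abs(mean(draws[, 2])), 3 * se[2])
  # centroid MSD of an isolated motile cell
  D <- 1e-16
  nst <- 1500
  msd <- numeric(100)
  tt <- NA
  for (r in 1:100) {
    s1 <- mech_state(list(cl), cfg = cfg, seed = r)
    dt <- stable_dt(s1)
    s1 <- advance_mechanics(s1, nst * dt, dt = dt)
    msd[r] <- sum(lumensim:::polygon_centroid(s1$cells[[1]]$xy)^2)
    tt <- nst * dt
  }
  expect_equal(mean(msd) / tt, 4 * D * 1e12, tolerance = 0.15)
})

test_that("with a stiff bulk modulus the enclosed area tracks the
          reference over a day", {
  cfg <- fast_cfg()
  cfg$dcm$K_V <- 2500
  cl <- build_cell(c(0, 0), 10, 24, "hepatoblast", cfg)
  cl$D <- 0
  st <- mech_state(list(cl), cfg = cfg)
  for (k in 1:24) st <- advance_mechanics(st, 3600)
  A <- lumensim:::polygon_area(st$cells[[1]]$xy)
  expect_lt(abs(A - st$cells[[1]]$Aref) / st$cells[[1]]$Aref, 0.01)
})
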