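# Scenario construction and the coupled simulation loop.

test_that("the bilayer has two rows with the active cells polarized", {
  cfg <- fast_cfg()
  set.seed(1)
  st <- build_bilayer(cfg, mechanism = "constriction", seed = 1,
                      relax_s = 0)
  expect_length(st$cells, 20)
  pol <- vapply(st$cells, function(cl) !is.null(cl$polarity), TRUE)
  expect_equal(sum(pol), 4)
  act <- which(vapply(st$cells, function(cl) isTRUE(cl$constricting), TRUE))
  expect_equal(length(act), 4)
  # apical vectors point toward the opposite layer
  for (i in act) expect_lt(st$cells[[i]]$polarity$abp[2], -0.9)
})

test_that("the duct system realizes the configured geometry", {
  cfg <- fast_cfg()
  set.seed(2)
  st <- build_duct_system(cfg, seed = 2, relax_s = 0)
  endo <- st$cbm[st$cbm$type == "endothelium", ]
  r <- sqrt(endo$x^2 + endo$y^2)
  expect_true(all(abs(r - 50) < max(endo$R)))
  expect_true(all(endo$fixed))
  # sampled cell sizes stay within the +-30% truncation of the mean
  hb <- st$cbm[st$cbm$type == "hepatoblast", ]
  expect_true(all(hb$birthR >= 7.5 * 0.7 - 1e-9 &
                    hb$birthR <= 7.5 * 1.3 + 1e-9))
  # founder: cholangiocyte, apical vector radially outward, tangential PCP
  fidx <- match(st$founder_id, vapply(st$cells, `[[`, 1L, "id"))
  fc <- st$cells[[fidx]]
  expect_equal(fc$type, "cholangiocyte")
  ctr <- lumensim:::polygon_centroid(fc$xy)
  rad <- ctr / sqrt(sum(ctr^2))
  expect_gt(sum(fc$polarity$abp * rad), 0.95)
  expect_lt(abs(sum(fc$polarity$pcp * rad)), 0.3)
  expect_true(fc$secreting)
})

test_that("background pressure loads only the outer hepatoblasts, inward", {
  cfg <- fast_cfg()
  set.seed(3)
  st <- build_duct_system(cfg, seed = 3, relax_s = 0)
  st0 <- apply_background_pressure(st, 0)
  expect_equal(max(abs(attr(st0, "forces"))), 0)
  stp <- apply_background_pressure(st, 50)
  F <- attr(stp, "forces")
  loaded <- which(rowSums(F^2) > 0)
  expect_gt(length(loaded), 3)
  r <- sqrt(stp$cbm$x^2 + stp$cbm$y^2)
  expect_true(all(r[loaded] >= stats::quantile(
    r[stp$cbm$type == "hepatoblast" & !stp$cbm$fixed], 0.9) - 1e-9))
  inward <- rowSums(F[loaded, , drop = FALSE] *
                      cbind(stp$cbm$x, stp$cbm$y)[loaded, , drop = FALSE])
  expect_true(all(inward < 0))
  # the loaded ring is closed and near-symmetric: forces nearly cancel
  expect_lt(max(abs(colSums(F))), 0.05 * sum(sqrt(rowSums(F^2))))
})

test_that("identical seeds give identical trajectories", {
  cfg <- fast_cfg()
  r1 <- run_bilayer("osmosis", cfg, seed = 7, duration = 0.25)
  r2 <- run_bilayer("osmosis", cfg, seed = 7, duration = 0.25)
  expect_identical(do.call(rbind, lapply(r1$cells, `[[`, "xy")),
                   do.call(rbind, lapply(r2$cells, `[[`, "xy")))
  expect_identical(r1$series$area, r2$series$area)
})

test_that("model variants map onto the feature switches", {
  expect_equal(model_variant(0),
               list(division = "random", apical_constriction = FALSE,
                    osmosis = FALSE))
  expect_equal(model_variant(1)$division, "oriented")
  expect_true(model_variant(2)$apical_constriction)
  expect_false(model_variant(2)$osmosis)
  expect_true(model_variant(3)$osmosis)
  expect_error(model_variant(4))
})

test_that("oriented divisions keep an epithelial arc single-layered", {
  cfg <- fast_cfg()
  set.seed(9)
  # a free arc of three polarized cells dividing along their PCP
  cells <- lapply(1:3, function(i) {
    cl <- build_cell(c((i - 2) * 19, 0), 10, 36, "cholangiocyte", cfg,
                     id = i)
    cl$polarity <- polarity_state(c(0, 1), pcp = c(1, 0))
    cl$D <- 0
    cl
  })
  st <- mech_state(cells, cfg = cfg)
  st <- advance_mechanics(st, 200)
  for (k in 1:3) {
    st <- divide_cell(st, k, "along_pcp")
    st <- advance_mechanics(st, 150)
  }
  ys <- vapply(st$cells, function(cl) lumensim:::polygon_centroid(cl$xy)[2],
               1)
  expect_lt(diff(range(ys)), 10)  # all centroids within one cell radius
})
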