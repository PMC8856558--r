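# Polarity vectors, surface-region classification, region-dependent
# adhesion and apical constriction.

test_that("region classification partitions the surface by cone angles", {
  cfg <- fast_cfg()
  cl <- build_cell(c(0, 0), 10, 72, "cholangiocyte", cfg)
  cl$polarity <- polarity_state(c(0, 1), alpha = pi / 6, gamma_tj = pi / 12)
  cl <- classify_regions(cl)
  L <- lumensim:::edge_lengths(cl$xy)
  fr_ap <- sum(L[cl$region == 1L]) / sum(L)
  # apical perimeter fraction = alpha/pi, within one element
  expect_lt(abs(fr_ap - (pi / 6) / pi), 1 / 72 + 1e-9)
  # the four regions partition the ring
  expect_equal(sum(L[cl$region == 0L]) + sum(L[cl$region == 1L]) +
                 sum(L[cl$region == 2L]) + sum(L[cl$region == 3L]),
               sum(L))
  # zero-width belt -> no tight-junction elements
  cl$polarity <- polarity_state(c(0, 1), alpha = pi / 6, gamma_tj = 0)
  cl <- classify_regions(cl)
  expect_equal(sum(cl$region == 3L), 0)
  # unpolarized cells are entirely lateral
  cl$polarity <- NULL
  cl <- classify_regions(cl)
  expect_true(all(cl$region == 0L))
})

test_that("region labels co-rotate with the cell and its polarity", {
  cfg <- fast_cfg()
  cl <- build_cell(c(0, 0), 10, 36, "cholangiocyte", cfg)
  cl$polarity <- polarity_state(c(0, 1))
  cl <- classify_regions(cl)
  ref <- cl$region
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- cl
  rot$xy <- cl$xy %*% t(R)
  rot$polarity <- polarity_state(as.vector(R %*% c(0, 1)))
  rot <- classify_regions(rot)
  expect_equal(rot$region, ref)
})

test_that("constriction shortens apical/TJ rest lengths and spares basal", {
  cfg <- fast_cfg()
  cl <- build_cell(c(0, 0), 10, 36, "cholangiocyte", cfg)
  cl$polarity <- polarity_state(c(0, 1))
  cl <- classify_regions(cl)
  same <- apply_constriction(cl, c(1, 1))
  expect_equal(same$rest, cl$base_rest, tolerance = 1e-12)
  con <- apply_constriction(cl, c(circumferential = 0.5, medioapical = 0.7))
  expect_equal(con$rest[cl$region == 1L], 0.7 * cl$base_rest[cl$region == 1L])
  expect_equal(con$rest[cl$region == 3L], 0.5 * cl$base_rest[cl$region == 3L])
  expect_equal(con$rest[cl$region == 2L], cl$base_rest[cl$region == 2L])
  expect_error(apply_constriction(cl, c(0, 0.5)), "factors")
  expect_error(apply_constriction(cl, c(0.5, 1.2)), "factors")
})

test_that("effective adhesion is symmetric with the printed energies", {
  expect_equal(effective_adhesion("apical", "apical"), 1e-6)
  expect_equal(effective_adhesion("lateral", "lateral"), 9e-4)
  expect_equal(effective_adhesion("tight_junction", "tight_junction"), 9e-3)
  labs <- c("lateral", "apical", "basal", "tight_junction")
  for (a in labs) for (b in labs) {
    expect_equal(effective_adhesion(a, b), effective_adhesion(b, a))
  }
})

test_that("the apical vector relaxes toward the free surface", {
  cfg <- fast_cfg()
  cl <- build_cell(c(0, 0), 10, 36, "cholangiocyte", cfg)
  cl$polarity <- polarity_state(c(1, 0))
  # free surface only on the +y quarter of the ring
  n <- 36
  nx <- c(2:n, 1)
  mid <- (cl$xy + cl$xy[nx, ]) / 2
  free <- mid[, 2] > 7
  for (k in 1:10) cl <- update_polarity(cl, free, dt = 1 / 6, tau_pol = 0.5)
  expect_lt(acos(sum(cl$polarity$abp * c(0, 1))), 0.12)
  expect_lt(abs(sum(cl$polarity$abp * cl$polarity$pcp)), 1e-9)
  # fully surrounded: unchanged
  cl2 <- build_cell(c(0, 0), 10, 36, "cholangiocyte", cfg)
  cl2$polarity <- polarity_state(c(1, 0))
  cl2 <- update_polarity(cl2, rep(FALSE, 36))
  expect_equal(cl2$polarity$abp, c(1, 0))
})
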