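# Center-based model: sphere-approximated cells with a modified JKR
# contact law, overdamped Langevin dynamics with pairwise drag coupling,
# and mechanically consistent coupling to the deformable cells.

#' JKR contact force between two sphere-approximated cells
#'
#' Classical Johnson-Kendall-Roberts adhesive contact on the fixed-grips
#' branch, with a density-correction multiplier on the elastic part at
#' relative overlaps above 5% (the multiplier table is calibrated against
#' a deformable-cell pair, see [calibrate_cbm_contact()]). Separations
#' beyond the detachment point give zero force; at `W = 0` the law reduces
#' to the Hertz force (4/3) E* sqrt(R*) delta^(3/2); the maximum adhesive
#' (pull-off) force is (3/2) pi W R*.
#'
#' @param delta Overlap(s) in um (negative = gap).
#' @param R1,R2 Cell radii (um).
#' @param E1,E2 Young's moduli (Pa).
#' @param nu1,nu2 Poisson ratios.
#' @param W Adhesion energy (J/m^2).
#' @param mult Density-correction table `list(x = delta/R*, y =
#'   multiplier)`, or `NULL` for the uncorrected law.
#' @return Force(s) in nN; positive = repulsive.
#' @export
#' @examples
#' jkr_force(0.1, 10, 10, W = 0)  # Hertz limit
jkr_force <- function(delta, R1, R2, E1 = 450, E2 = E1, nu1 = 0.47,
                      nu2 = nu1, W = 9e-4, mult = jkr_mult_default()) {
  if (is.null(mult)) mult <- list(x = numeric(), y = numeric())
  cpp_jkr_force(as.numeric(delta), R1, R2, pa2int(E1), pa2int(E2), nu1, nu2,
                W * 1000, mult$x, mult$y)
}

#' Add center-based cells to a state
#'
#' @param state A [mech_state()].
#' @param x,y Centers (um).
#' @param R Radii (um).
#' @param type Cell type string.
#' @param fixed Immobile (e.g. portal-vein endothelium)?
#' @param quiescent Excluded from growth?
#' @param age Cycle ages (h); sampled uniformly over the first half-cycle
#'   for cycling cells when missing. Cells are placed at their age-grown
#'   radius `R * sqrt(1 + age/tau)`.
#' @param cfg Configuration (CBM elastic constants, motility, cycle time).
#' @return The state with rows appended to `state$cbm`.
#' @export
add_cbm_cells <- function(state, x, y, R, type = "hepatoblast",
                          fixed = FALSE, quiescent = fixed, age = NULL,
                          cfg = state$config) {
  n <- length(x)
  ids <- state$next_id + seq_len(n) - 1L
  state$next_id <- state$next_id + n
  cv <- cfg$cell$cycle_cv
  tau <- cfg$cell$cycle_time *
    pmax(1 - 3 * cv, pmin(1 + 3 * cv, 1 + cv * rnorm(n)))
  if (is.null(age)) {
    age <- if (quiescent[1]) rep(0, n) else stats::runif(n, 0, 0.5) * tau
  }
  state$cbm <- rbind(state$cbm, data.frame(
    id = ids, x = x, y = y, R = R * sqrt(1 + age / tau), E = cfg$cbm$E,
    nu = cfg$cbm$nu, type = type, fixed = fixed, quiescent = quiescent,
    tau = tau, age = age,
    birthR = R, D = cfg$cbm$D, Wmul = 1, fx = 0, fy = 0))
  state
}

#' Hybrid DCM-CBM contact forces
#'
#' A center-based cell is presented to the deformable cells as a rigid
#' circular boundary interacting through the same cohesive-zone law as
#' cell-cell contacts; the reaction force is accumulated on the center.
#'
#' @param state A [mech_state()] containing DCM and CBM cells.
#' @return List with `F` (nodal forces) and `Fcbm` (center forces), nN.
#' @export
hybrid_contact_forces <- function(state) {
  out <- forces_raw(state, force_mask["contact"])
  list(F = out$F, Fcbm = out$Fcbm)
}

#' Calibrate the modified JKR law against a deformable-cell pair
#'
#' Presses two deformable cells together with stepwise increasing external
#' body forces, relaxes to equilibrium at each step, measures the
#' force-overlap response, and expresses it as a stiffening multiplier on
#' the elastic part of the JKR law (relative to the CBM elastic
#' constants). The first point is the force-free adhesive equilibrium, so
#' a calibrated CBM pair relaxes to the same spacing as the DCM pair.
#'
#' @param cfg Configuration.
#' @param radius Cell radius (um).
#' @param forces Compression body forces per cell (nN) defining the
#'   sampled overlap range.
#' @param relax_s Relaxation time per force step (s).
#' @return `list(x = delta/R*, y = multiplier)` usable as the `mult`
#'   argument of [jkr_force()].
#' @export
calibrate_cbm_contact <- function(cfg = default_config(), radius = 10,
                                  forces = c(0, 2, 5, 10, 20),
                                  relax_s = 240) {
  n <- nodes_for_radius(radius, cfg)
  a <- build_cell(c(-radius + 1, 0), radius, n, "hepatoblast", cfg, id = 1L)
  b <- build_cell(c(radius - 1, 0), radius, n, "hepatoblast", cfg, id = 2L)
  a$D <- 0; b$D <- 0
  st <- mech_state(list(a, b), cfg = cfg)
  Rs <- radius / 2
  Es <- 1 / (2 * (1 - cfg$cbm$nu^2) / pa2int(cfg$cbm$E))
  w <- w_line(cfg$dcm$W, cfg$dcm$h_z) / cfg$dcm$h_z
  xs <- ys <- numeric(0)
  for (F in forces) {
    st$cells[[1]]$fext <- c(+F, 0)
    st$cells[[2]]$fext <- c(-F, 0)
    st <- advance_mechanics(st, relax_s)
    R1 <- cell_radius_eff(st$cells[[1]])
    R2 <- cell_radius_eff(st$cells[[2]])
    d12 <- sqrt(sum((polygon_centroid(st$cells[[1]]$xy) -
                       polygon_centroid(st$cells[[2]]$xy))^2))
    delta <- R1 + R2 - d12
    ac <- jkr_a_of_delta_r(delta, Rs, Es, w)
    if (is.na(ac)) next
    hertz <- (4 / 3) * Es * ac^3 / Rs
    adh <- sqrt(8 * pi * w * Es * ac^3)
    xs <- c(xs, delta / Rs)
    ys <- c(ys, (F + adh) / hertz)
  }
  keep <- !duplicated(xs) & xs > 0.05
  xs <- xs[keep]; ys <- pmax(ys[keep], 1e-3)
  o <- order(xs)
  # anchor at the 5% threshold where the correction switches on
  list(x = c(0.05, xs[o]), y = c(1, ys[o]))
}

# R-side solve of the JKR delta(a) relation (used by the calibration)
jkr_a_of_delta_r <- function(delta, Rs, Es, w) {
  dofa <- function(a) a^2 / Rs - sqrt(2 * pi * w * a / Es)
  admin <- (0.25 * Rs * sqrt(2 * pi * w / Es))^(2 / 3)
  if (delta < dofa(admin)) return(NA_real_)
  hi <- 2 * admin
  while (dofa(hi) < delta) hi <- hi * 2
  stats::uniroot(function(a) dofa(a) - delta, c(admin, hi),
                 tol = 1e-12)$root
}
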