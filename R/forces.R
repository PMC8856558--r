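# Force-term API and the matching potential energies. Forces are computed
# by the compiled core; the energies here are independent R
# implementations of the same potentials, used by the gradient tests and
# the relaxation (energy-descent) audit. Every conservative force term is
# the exact negative gradient of the corresponding energy below.

single_state <- function(cell, cfg = default_config()) {
  cell$id <- 1L
  mech_state(list(cell), cfg = cfg)
}

force_mask <- c(inplane = 1L, bending = 2L, volume = 4L, contact = 8L,
                osmotic = 16L)

forces_raw <- function(state, mask) {
  flat <- flatten_state(state)
  par <- internal_params(state$config, dt = 1, P_L = state$P_L,
                         seed = state$seed, counter = state$counter)
  cpp_forces(flat, par, as.integer(mask))
}

split_by_cell <- function(state, F) {
  npc <- vapply(state$cells, function(cl) nrow(cl$xy), 1L)
  off <- c(0L, cumsum(npc))
  lapply(seq_along(state$cells), function(c) {
    F[(off[c] + 1):off[c + 1], , drop = FALSE]
  })
}

#' In-plane (cortex spring) forces of a cell
#'
#' Linear springs along the ring elements, stiffness from the cortex
#' sheet modulus E_cor * h_cor over the slab depth. Forces sum to zero
#' over the cell.
#'
#' @param cell A [build_cell()] object.
#' @param cfg Configuration.
#' @return n x 2 matrix of nodal forces (nN).
#' @export
inplane_forces <- function(cell, cfg = default_config()) {
  forces_raw(single_state(cell, cfg), force_mask["inplane"])$F
}

#' Cortex bending forces of a cell
#'
#' Discrete curvature penalty on the turning angle at each node, with the
#' spontaneous angle of the regular polygon at birth. Zero net force and
#' zero net torque.
#' @inheritParams inplane_forces
#' @return n x 2 matrix of nodal forces (nN).
#' @export
bending_forces <- function(cell, cfg = default_config()) {
  forces_raw(single_state(cell, cfg), force_mask["bending"])$F
}

#' Volume-control forces of a cell
#'
#' Pressure p = K_V (1 - A/A_ref) applied along the outward normal of each
#' element and lumped to its nodes (the exact area gradient).
#' @inheritParams inplane_forces
#' @return n x 2 matrix of nodal forces (nN).
#' @export
volume_force <- function(cell, cfg = default_config()) {
  if (polygon_area(cell$xy) <= 0) {
    stop("degenerate geometry: enclosed area must be positive")
  }
  forces_raw(single_state(cell, cfg), force_mask["volume"])$F
}

#' Cell-cell contact forces (cohesive-zone law)
#'
#' Adhesion and repulsion between two deformable cells: each node
#' interacts with the nearest surface element of the other cell through a
#' piecewise-linear cohesive traction whose work of separation per unit
#' contact length equals the pairwise effective adhesion energy
#' ([effective_adhesion()]); linear repulsion prevents interpenetration.
#'
#' @param cell_a,cell_b Two [build_cell()] objects.
#' @param cfg Configuration.
#' @return List with `Fa`, `Fb` (nodal force matrices, nN); exact
#'   action-reaction: `colSums(Fa) == -colSums(Fb)`.
#' @export
contact_forces <- function(cell_a, cell_b, cfg = default_config()) {
  cell_a$id <- 1L; cell_b$id <- 2L
  st <- mech_state(list(cell_a, cell_b), cfg = cfg)
  F <- forces_raw(st, force_mask["contact"])$F
  sp <- split_by_cell(st, F)
  list(Fa = sp[[1]], Fb = sp[[2]])
}

#' Osmotic pressure forces on marked surface elements
#'
#' A constant lumen pressure `P_L` loads every osmotically marked (free,
#' cavity-facing) element along the inward normal, pushing the cell
#' surface away from the marked cavity; magnitude P_L x element length x
#' slab depth.
#'
#' @param state A [mech_state()].
#' @param P_L Lumen pressure (Pa).
#' @return N x 2 matrix of nodal forces over all cells (nN).
#' @export
osmotic_forces <- function(state, P_L) {
  state$P_L <- P_L
  forces_raw(state, force_mask["osmotic"])$F
}

#' Migration (motility) force of a cell
#'
#' One Brownian force per cell and step, zero mean and uncorrelated in
#' time, distributed equally on all nodes, calibrated so that a free
#' cell's centroid diffuses with coefficient `D`.
#'
#' @param cell A [build_cell()] object.
#' @param D Motility (m^2/s).
#' @param dt Timestep (s) for which the force will be applied.
#' @param cfg Configuration (sets the free-surface friction).
#' @return n x 2 matrix of identical per-node forces (nN).
#' @export
migration_force <- function(cell, D, dt, cfg = default_config()) {
  n <- nrow(cell$xy)
  if (D <= 0) return(matrix(0, n, 2))
  g <- gamma2int(max(cfg$dcm$gamma_ECM, cfg$dcm$gamma_liq), cfg$dcm$h_z) +
    gamma2int(cfg$dcm$gamma_int, cfg$dcm$h_z)
  l0n <- (cell$rest + cell$rest[c(n, seq_len(n - 1))]) / 2
  G <- sum(g * l0n)
  s <- G * sqrt(2 * d2int(D) / dt)
  Fc <- rnorm(2, 0, s)
  matrix(rep(Fc / n, each = n), n, 2)
}

# ---------------------------------------------------------------------
# Energies (independent R mirrors of the compiled force terms)
# ---------------------------------------------------------------------

# per-side cohesive-zone potential per unit node length
cohesive_u <- function(d, Epair, h, krep) {
  t0 <- Epair / (1.5 * h)
  hc <- 0.5 * h
  Uhc <- -0.5 * t0 * (h - hc)
  U0 <- Uhc - t0 * hc
  ifelse(d >= h, 0,
    ifelse(d >= hc, -0.5 * t0 * (h - d)^2 / (h - hc),
      ifelse(d >= 0, Uhc - t0 * (hc - d),
        U0 + t0 * d + 0.5 * krep * d^2)))
}

#' Potential energy of a state, by term
#'
#' Independent R implementation of the potentials whose negative gradients
#' are the compiled force terms: cortex springs, bending, volume control,
#' cohesive-zone contact (including contacts with CBM discs) and the
#' osmotic loading potential. Used by the package's gradient-consistency
#' and energy-descent tests.
#'
#' @param state A [mech_state()].
#' @param term One of `"inplane"`, `"bending"`, `"volume"`, `"contact"`,
#'   `"osmotic"`, `"total"`.
#' @return Energy in nN um.
#' @export
dcm_energy <- function(state, term = "total") {
  terms <- if (identical(term, "total")) {
    c("inplane", "bending", "volume", "contact", "osmotic")
  } else term
  cfg <- state$config
  E <- 0
  for (tm in terms) E <- E + switch(tm,
    inplane = sum(vapply(state$cells, function(cl) {
      L <- edge_lengths(cl$xy)
      sum(0.5 * cl$kel * (L - cl$rest)^2)
    }, 1)),
    bending = sum(vapply(state$cells, function(cl) {
      n <- nrow(cl$xy)
      nx <- c(2:n, 1); pv <- c(n, 1:(n - 1))
      e1 <- cl$xy - cl$xy[pv, , drop = FALSE]
      e2 <- cl$xy[nx, , drop = FALSE] - cl$xy
      th <- atan2(e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1],
                  e1[, 1] * e2[, 1] + e1[, 2] * e2[, 2])
      sum(0.5 * cl$kb * (th - cl$th0)^2)
    }, 1)),
    volume = sum(vapply(state$cells, function(cl) {
      if (isTRUE(cl$fixed)) return(0)
      A <- polygon_area(cl$xy)
      cl$KV / (2 * cl$Aref) * (A - cl$Aref)^2
    }, 1)),
    contact = contact_energy(state),
    osmotic = {
      PL <- p_line(state$P_L, cfg$dcm$h_z)
      sum(vapply(state$cells, function(cl) {
        if (!any(cl$marked == 1L)) return(0)
        n <- nrow(cl$xy)
        nx <- c(2:n, 1)
        cr <- cl$xy[, 1] * cl$xy[nx, 2] - cl$xy[nx, 1] * cl$xy[, 2]
        PL * sum(0.5 * cr[cl$marked == 1L])
      }, 1))
    },
    stop("unknown energy term: ", tm))
  E
}

# cohesive contact energy: per node, nearest interior-projection element
# of each other cell (and each CBM disc), mirroring the core's pairing
contact_energy <- function(state) {
  cfg <- state$config
  cells <- state$cells
  C <- length(cells)
  h <- cfg$dcm$h_int
  krep <- cfg$dcm$k_rep
  wl <- lapply(cells, function(cl) w_side_line(cl$region, cfg) * cl$Wmul)
  E <- 0
  for (a in seq_len(C)) {
    xy <- cells[[a]]$xy
    n <- nrow(xy)
    l0n <- (cells[[a]]$rest + cells[[a]]$rest[c(n, seq_len(n - 1))]) / 2
    for (i in seq_len(n)) {
      x <- xy[i, 1]; y <- xy[i, 2]
      for (b in seq_len(C)) {
        if (b == a) next
        oxy <- cells[[b]]$xy
        m <- nrow(oxy)
        nx2 <- c(2:m, 1)
        dx <- oxy[nx2, 1] - oxy[, 1]; dy <- oxy[nx2, 2] - oxy[, 2]
        L2 <- pmax(dx^2 + dy^2, 1e-18)
        t <- ((x - oxy[, 1]) * dx + (y - oxy[, 2]) * dy) / L2
        interior <- t > 0 & t < 1
        L <- sqrt(L2)
        d <- ifelse(interior,
          (x - (oxy[, 1] + t * dx)) * (dy / L) +
            (y - (oxy[, 2] + t * dy)) * (-dx / L),
          {
            qx <- ifelse(t <= 0, oxy[, 1], oxy[nx2, 1])
            qy <- ifelse(t <= 0, oxy[, 2], oxy[nx2, 2])
            sqrt((x - qx)^2 + (y - qy)^2)
          })
        j <- which.min(abs(d))
        dj <- d[j]
        if (!interior[j] &&
            as.logical(cpp_points_in_ring(matrix(c(x, y), 1, 2), oxy))) {
          dj <- -dj
        }
        Epair <- min(wl[[a]][i], wl[[b]][j])
        E <- E + l0n[i] * cohesive_u(dj, Epair, h, krep)
      }
      if (nrow(state$cbm)) {
        for (j in seq_len(nrow(state$cbm))) {
          d <- sqrt((x - state$cbm$x[j])^2 + (y - state$cbm$y[j])^2) -
            state$cbm$R[j]
          Epair <- min(wl[[a]][i],
                        w_line(cfg$dcm$W, cfg$dcm$h_z) * state$cbm$Wmul[j])
          E <- E + l0n[i] * cohesive_u(d, Epair, h, krep)
        }
      }
    }
  }
  E
}
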