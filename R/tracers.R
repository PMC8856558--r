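# Tracer particles: discrete proxies for secreted ion clouds. They are
# created at the centre of secreting cholangiocytes, random-walk without
# interacting with each other, may leave a cell only outward through a
# free apical surface element, never cross any other cell surface, and
# mark free surface elements they touch; marked elements carry the
# constant osmotic lumen pressure P_L.

#' Secrete tracer particles
#'
#' Every secreting cholangiocyte creates Poisson(rate * dt) new
#' intracellular particles at its centroid. Cells of other types, or
#' cholangiocytes with secretion disabled, create none. A per-cell cap on
#' live particles bounds the population (the marked-surface geometry, not
#' the particle count, feeds the mechanics).
#'
#' @param state A [mech_state()].
#' @param dt Elapsed time (h).
#' @param rate Particles per hour per secreting cell.
#' @return The state with new particles appended.
#' @export
secrete <- function(state, dt, rate = state$config$tracer$rate) {
  cap <- state$config$tracer$max_per_cell
  for (cl in state$cells) {
    if (!identical(cl$type, "cholangiocyte") || !isTRUE(cl$secreting)) next
    live <- sum(state$particles$origin == cl$id)
    n <- rpois(1, rate * dt)
    n <- min(n, max(0L, cap - live))
    if (n <= 0) next
    ctr <- polygon_centroid(cl$xy)
    ids <- state$next_tp + seq_len(n) - 1L
    state$next_tp <- state$next_tp + n
    state$particles <- rbind(state$particles, data.frame(
      id = ids, x = ctr[1], y = ctr[2], owner = cl$id, origin = cl$id))
  }
  state
}

#' Diffuse tracer particles and transfer them across apical surfaces
#'
#' Advances every particle by a Gaussian random-walk step of standard
#' deviation sqrt(2 D_tp dt) per axis (cell surfaces frozen).
#' An intracellular particle whose step crosses its cell ring is let
#' through only outward through a free apical element (it becomes
#' extracellular); crossings anywhere else - in particular through
#' tight-junction-sealed cell-cell contacts - are rejected. Extracellular
#' particles never cross any cell surface. Extracellular particles mark
#' free surface elements within the capture radius.
#'
#' @param state A [mech_state()].
#' @param seconds Diffusion time (s).
#' @param nsteps Number of random-walk steps to split `seconds` into.
#' @return The state with particles moved, compartments updated and marks
#'   added.
#' @export
diffuse_and_transfer <- function(state, seconds, nsteps = 1L) {
  if (!nrow(state$particles)) return(state)
  flat <- flatten_state(state)
  par <- internal_params(state$config, dt = 1, P_L = state$P_L,
                         seed = state$seed, counter = state$counter)
  out <- cpp_tracers_only(flat, par, as.integer(nsteps), seconds / nsteps)
  state$counter <- state$counter + 1
  out$elem_contact <- rep(0L, sum(vapply(state$cells, function(cl) nrow(cl$xy), 1L)))
  st <- unflatten_state(state, flat, out)
  st$last_contact <- NULL
  st
}

#' Refresh osmotic surface marks
#'
#' Clears the mark of every element that is (again) in cell-cell contact,
#' then marks every free element within the capture radius of an
#' extracellular tracer particle.
#'
#' @param state A [mech_state()].
#' @return The state with updated element marks.
#' @export
mark_surfaces <- function(state) {
  cls <- classify_contacts(state)
  off <- cls$off
  gap_close <- state$config$numerics$gap_close
  for (c in seq_along(state$cells)) {
    eg <- cls$elem_gap[(off[c] + 1):off[c + 1]]
    state$cells[[c]]$marked[eg < gap_close] <- 0L
  }
  if (!nrow(state$particles)) return(state)
  diffuse_and_transfer(state, 0, 1L)
}


# preload a handful of particles at the centre of a newly secreting cell
# (secretion is already under way when the cell appears)
seed_secretion <- function(state, cell_id, n = 20L) {
  idx <- match(cell_id, vapply(state$cells, `[[`, 1L, "id"))
  ctr <- polygon_centroid(state$cells[[idx]]$xy)
  ids <- state$next_tp + seq_len(n) - 1L
  state$next_tp <- state$next_tp + n
  state$particles <- rbind(state$particles, data.frame(
    id = ids, x = ctr[1], y = ctr[2], owner = cell_id, origin = cell_id))
  state
}


# Region-level mark refresh: the osmotic pressure acts on the walls of
# the ion-rich extracellular region, so every unsealed element within
# reach of an extracellular particle is marked and all others cleared.
# The in-step particle-capture marking adds responsiveness between
# refreshes; this recomputation removes any marking hysteresis.
remark_lumen <- function(state, cls, reach = 3) {
  off <- cls$off
  gap_close <- state$config$numerics$gap_close
  pp <- state$particles[state$particles$owner == 0L, , drop = FALSE]
  if (!nrow(pp)) return(state)
  for (c in seq_along(state$cells)) {
    cl <- state$cells[[c]]
    n <- nrow(cl$xy)
    eg <- cls$elem_gap[(off[c] + 1):off[c + 1]]
    nx <- c(2:n, 1)
    mid <- (cl$xy + cl$xy[nx, , drop = FALSE]) / 2
    d2 <- vapply(seq_len(n), function(e) {
      min((mid[e, 1] - pp$x)^2 + (mid[e, 2] - pp$y)^2)
    }, 1)
    # additive: sustained closure (tracked in the mechanics core) clears
    state$cells[[c]]$marked <-
      as.integer(cl$marked == 1L | (eg > gap_close & d2 < reach^2))
  }
  state
}
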