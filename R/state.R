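# Simulation state: DCM cells, CBM cells, tracer particles, clock and RNG
# bookkeeping, plus the flatten/unflatten layer between R objects and the
# C++ mechanics core.

#' Create a mechanics state
#'
#' @param cells List of [build_cell()] objects.
#' @param cbm Data frame of center-based cells (see [new_cbm_cells()]), or
#'   `NULL`.
#' @param cfg Configuration list.
#' @param seed Master seed of this realization.
#' @return An object of class `mech_state`: cells, CBM table, tracer
#'   particles, simulated time (h) and RNG bookkeeping.
#' @export
mech_state <- function(cells = list(), cbm = NULL, cfg = default_config(),
                       seed = 1L) {
  if (is.null(cbm)) cbm <- new_cbm_cells()
  ids <- vapply(cells, `[[`, 1L, "id")
  if (anyDuplicated(c(ids, cbm$id))) stop("duplicate cell ids")
  structure(list(
    cells = cells,
    cbm = cbm,
    particles = data.frame(id = integer(), x = numeric(), y = numeric(),
                           owner = integer(), origin = integer()),
    time = 0,
    config = cfg,
    seed = as.integer(seed),
    counter = 0,
    next_id = as.integer(max(c(0L, ids, cbm$id)) + 1L),
    next_tp = 1L,
    P_L = 0,
    events = data.frame(time = numeric(), event = character(),
                        cell = integer(), detail = character())
  ), class = "mech_state")
}

#' Empty table of center-based cells
#'
#' Columns: id, x, y (um), R (um), E (Pa), nu, type, fixed, quiescent,
#' tau (h), age (h), birthR (um), D (m^2/s), Wmul, fx, fy (external force,
#' nN).
#' @return A zero-row data frame with the CBM schema.
#' @export
new_cbm_cells <- function() {
  data.frame(id = integer(), x = numeric(), y = numeric(), R = numeric(),
             E = numeric(), nu = numeric(), type = character(),
             fixed = logical(), quiescent = logical(), tau = numeric(),
             age = numeric(), birthR = numeric(), D = numeric(),
             Wmul = numeric(), fx = numeric(), fy = numeric())
}

#' @export
print.mech_state <- function(x, ...) {
  cat(sprintf("<mech_state: t = %.2f h, %d DCM cells, %d CBM cells, %d tracers>\n",
              x$time, length(x$cells), nrow(x$cbm), nrow(x$particles)))
  invisible(x)
}

add_event <- function(state, event, cell = NA_integer_, detail = "") {
  state$events <- rbind(state$events, data.frame(
    time = state$time, event = event, cell = as.integer(cell),
    detail = detail))
  state
}

# ---------------------------------------------------------------------
# flatten / unflatten
# ---------------------------------------------------------------------
flatten_state <- function(state) {
  cells <- state$cells
  cfg <- state$config
  C <- length(cells)
  npc <- vapply(cells, function(cl) nrow(cl$xy), 1L)
  off <- as.integer(c(0L, cumsum(npc)))
  pos <- if (C) do.call(rbind, lapply(cells, `[[`, "xy")) else
    matrix(0, 0, 2)
  getv <- function(f) if (C) unlist(lapply(cells, `[[`, f), use.names = FALSE) else numeric()
  region <- as.integer(getv("region"))
  wm <- rep(vapply(cells, `[[`, 1, "Wmul"), npc)
  welem <- w_side_line(region, cfg) * wm
  cb <- state$cbm
  cbm <- cbind(cb$x, cb$y, cb$R,
               pa2int(cb$E), cb$nu,
               w_line(cfg$dcm$W, cfg$dcm$h_z) * cb$Wmul,
               d2int(cb$D), cb$fx, cb$fy)
  if (!nrow(cb)) cbm <- matrix(0, 0, 9)
  tp <- state$particles
  owner_idx <- integer(nrow(tp))
  if (nrow(tp)) {
    ids <- vapply(cells, `[[`, 1L, "id")
    owner_idx <- ifelse(tp$owner > 0L, match(tp$owner, ids), tp$owner)
    owner_idx[is.na(owner_idx)] <- -1L  # owner vanished; retire
  }
  list(
    pos = pos,
    off = off,
    rest = getv("rest"),
    rest0 = getv("rest0"),
    kel = getv("kel"),
    cfac = getv("cfac"),
    welem = welem,
    region = region,
    marked = as.integer(getv("marked")),
    Aref = vapply(cells, `[[`, 1, "Aref"),
    KV = vapply(cells, function(cl) if (isTRUE(cl$fixed)) 0 else cl$KV, 1),
    kb = vapply(cells, `[[`, 1, "kb"),
    th0 = vapply(cells, `[[`, 1, "th0"),
    Dmig = vapply(cells, `[[`, 1, "D"),
    cfx = vapply(cells, function(cl) cl$fext[1], 1),
    cfy = vapply(cells, function(cl) cl$fext[2], 1),
    cid = vapply(cells, `[[`, 1L, "id"),
    cfixed = as.integer(vapply(cells, function(cl) isTRUE(cl$fixed), TRUE)),
    cbm = cbm,
    cbm_fixed = as.integer(cb$fixed),
    cbm_id = as.integer(cb$id),
    tp = cbind(tp$x, tp$y, as.numeric(owner_idx), as.numeric(tp$id))
  )
}

unflatten_state <- function(state, flat, out) {
  cells <- state$cells
  C <- length(cells)
  off <- flat$off
  pos <- out$pos
  marked <- out$marked
  kcoef <- pa2int(state$config$dcm$E_cor) *
    (state$config$dcm$h_cor * 1e-3) * state$config$dcm$h_z
  for (c in seq_len(C)) {
    idx <- (off[c] + 1):off[c + 1]
    cells[[c]]$xy <- pos[idx, , drop = FALSE]
    cells[[c]]$marked <- as.integer(marked[idx])
    # cortical viscoelastic remodeling updates the rest lengths
    rst <- out$rest[idx]
    cells[[c]]$rest <- rst
    cells[[c]]$kel <- kcoef / rst
    cells[[c]]$base_rest <- rst / cells[[c]]$cfac
  }
  state$cells <- cells
  if (nrow(state$cbm)) {
    state$cbm$x <- out$cbm_pos[, 1]
    state$cbm$y <- out$cbm_pos[, 2]
  }
  tp <- out$tp
  if (nrow(state$particles)) {
    ids <- vapply(cells, `[[`, 1L, "id")
    own <- as.integer(tp[, 3])
    own[own > 0L] <- ids[own[own > 0L]]
    keep <- own >= 0L
    state$particles <- data.frame(id = as.integer(tp[keep, 4]),
                                  x = tp[keep, 1], y = tp[keep, 2],
                                  owner = own[keep],
                                  origin = state$particles$origin[keep])
  }
  ec <- as.integer(out$elem_contact)
  state$last_contact <- lapply(seq_len(C), function(c) {
    ec[(off[c] + 1):off[c + 1]]
  })
  state
}

#' Advance the mechanics by a time interval
#'
#' Runs the overdamped explicit-Euler integration (forces, friction,
#' tracer transport, osmotic loading) for `seconds` of simulated time.
#' Event-level processes (growth, division, fate, polarity) are not
#' touched; [run_model()] interleaves them.
#'
#' @param state A [mech_state()].
#' @param seconds Simulated seconds to advance.
#' @param dt Substep in seconds; default [stable_dt()].
#' @return The advanced state.
#' @export
advance_mechanics <- function(state, seconds, dt = NULL) {
  if (is.null(dt)) dt <- stable_dt(state)
  nsub <- max(1L, as.integer(ceiling(seconds / dt)))
  if (nsub >= 100000L) stop("advance interval too long for one call; split it")
  flat <- flatten_state(state)
  par <- internal_params(state$config, dt = seconds / nsub, P_L = state$P_L,
                         seed = state$seed, counter = state$counter)
  out <- cpp_advance(flat, par, nsub)
  if (!isTRUE(out$ok)) {
    stop("non-finite force encountered; state dumped to attribute",
         call. = FALSE)
  }
  state$counter <- state$counter + 1
  unflatten_state(state, flat, out)
}

#' Single integration step
#'
#' One explicit Euler step of the overdamped node dynamics: velocities
#' solve the diagonal friction balance, positions advance by `v * dt`,
#' out-of-plane motion is identically zero (the state is planar).
#'
#' @param state A [mech_state()].
#' @param dt Timestep (s).
#' @return Advanced state.
#' @export
step <- function(state, dt) advance_mechanics(state, dt, dt = dt)

# classification wrapper: element/node contact flags and partners.
# h_int overrides the interaction range (e.g. the lumen measurement closes
# sub-micron necks by classifying with a wider radius).
classify_contacts <- function(state, h_int = NULL) {
  flat <- flatten_state(state)
  par <- internal_params(state$config, dt = 1, P_L = state$P_L,
                         seed = state$seed, counter = state$counter)
  if (!is.null(h_int)) par$h_int <- h_int
  cls <- cpp_classify_contacts(flat, par)
  cls$off <- flat$off
  cls$cellof <- rep(seq_along(state$cells),
                    vapply(state$cells, function(cl) nrow(cl$xy), 1L))
  cls
}
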