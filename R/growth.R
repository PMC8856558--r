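# Cell growth, the five-stage division algorithm, the proliferation-rate
# controller and hepatoblast-to-cholangiocyte differentiation.

#' Grow a cell
#'
#' The reference volume ramps linearly in (cycling) time from the birth
#' volume to twice the birth volume at the cycle time tau; quiescent cells
#' do not grow. Division is triggered by the caller once the reference
#' volume has doubled.
#'
#' @param cell A [build_cell()] object.
#' @param dt Elapsed time (h).
#' @return The grown cell.
#' @export
grow <- function(cell, dt) {
  if (isTRUE(cell$quiescent) || isTRUE(cell$fixed)) return(cell)
  cell$age <- cell$age + dt
  cell$Aref <- cell$birthA * (1 + cell$age / cell$tau)
  cell
}

ready_to_divide <- function(cell) {
  !isTRUE(cell$fixed) && cell$Aref >= 2 * cell$birthA - 1e-9
}

#' Division axis
#'
#' Oriented division is along the planar polarity vector; random division
#' draws the axis angle uniformly on `[0, pi)`.
#'
#' @param polarity A [polarity_state()] or `NULL`.
#' @param mode `"along_pcp"` or `"random"`.
#' @return Unit 2-vector.
#' @export
division_axis <- function(polarity, mode = c("along_pcp", "random")) {
  mode <- match.arg(mode)
  if (mode == "along_pcp") {
    if (is.null(polarity)) stop("oriented division needs a polarized cell")
    return(polarity$pcp)
  }
  a <- runif(1, 0, pi)
  c(cos(a), sin(a))
}

#' Divide a deformable cell
#'
#' Five-stage division: the mother envelope is frozen in place, a division
#' axis is chosen (along the PCP vector or at random), two small daughter
#' rings are seeded on either side of the centroid inside the envelope and
#' grown artificially fast in a confined sub-simulation until together
#' they fill the mother volume; the envelope is then removed and the
#' daughters (which inherit type, polarity and parameters, with the cycle
#' time resampled at +-10%) adhere and adapt to the surroundings.
#'
#' @param state A [mech_state()].
#' @param idx Index of the mother cell in `state$cells`.
#' @param mode `"along_pcp"` or `"random"`.
#' @return The state with the mother replaced by two daughters.
#' @export
divide_cell <- function(state, idx, mode = c("along_pcp", "random")) {
  mode <- match.arg(mode)
  cfg <- state$config
  mother <- state$cells[[idx]]
  n <- nrow(mother$xy)
  if (n < 24) {
    stop("refusing to divide a ring with fewer than 24 nodes")
  }
  # stage 1-2: mitotic round-up. Adhesion is released (cadherins
  # internalized) and any constriction is relaxed; cortex tension and
  # volume control round the cell up in place before the plane is chosen.
  state$cells[[idx]]$Wmul <- 1e-6
  state$cells[[idx]]$rest <- mother$base_rest
  state$cells[[idx]]$kel <- mother$kel0
  state$cells[[idx]]$cfac <- rep(1, n)
  state$cells[[idx]]$D <- 0
  state <- advance_mechanics(state, 240)
  mother$xy <- state$cells[[idx]]$xy
  ax <- division_axis(mother$polarity, mode)
  Am <- polygon_area(mother$xy)
  ctr <- polygon_centroid(mother$xy)
  Reff <- sqrt(Am / pi)
  Rt <- sqrt(Am / 2 / pi)   # target daughter radius
  seedR <- 0.42 * Reff

  # stage 1-3: frozen mother envelope (reversed ring so its normals face
  # the daughters), two daughter seeds with target-geometry rest lengths
  env <- new_cell_from_ring(mother$xy[n:1, , drop = FALSE], "envelope", cfg,
                            id = 1L, allow_cw = TRUE)
  env$D <- 0
  mk_daughter <- function(sgn, id) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cen <- ctr + sgn * 0.38 * Reff * ax
    xy <- cbind(cen[1] + seedR * cos(th), cen[2] + seedR * sin(th))
    d <- new_cell_from_ring(xy, mother$type, cfg, id = id,
                            rest = rep(2 * Rt * sin(pi / n), n))
    d$Aref <- pi * seedR^2
    d$D <- 0   # no micro-motility inside the mother envelope
    d
  }
  sub <- mech_state(list(env, mk_daughter(-1, 2L), mk_daughter(1, 3L)),
                    cfg = cfg, seed = state$seed)
  sub$counter <- state$counter
  dt_sub <- stable_dt(sub) / 3
  # artificially fast growth (200x nominal), confined by the envelope
  rate <- 200 * (Am / 2) / (mother$tau * 3600)   # um^2/s per daughter
  A0 <- pi * seedR^2
  Tgrow <- (Am / 2 - A0) / rate
  nchunk <- 24L
  for (k in seq_len(nchunk)) {
    frac <- k / nchunk
    sub$cells[[2]]$Aref <- A0 + frac * (Am / 2 - A0)
    sub$cells[[3]]$Aref <- A0 + frac * (Am / 2 - A0)
    sub <- advance_mechanics(sub, Tgrow / nchunk, dt = dt_sub)
  }
  # drive the actual daughter areas to the mother's (cytoplasm volume
  # conservation): inflate the reference until the enclosed areas match
  for (it in seq_len(25)) {
    Asum <- polygon_area(sub$cells[[2]]$xy) + polygon_area(sub$cells[[3]]$xy)
    if (Asum >= 0.98 * Am) break
    sub$cells[[2]]$Aref <- sub$cells[[2]]$Aref * 1.03
    sub$cells[[3]]$Aref <- sub$cells[[3]]$Aref * 1.03
    sub <- advance_mechanics(sub, 25, dt = dt_sub)
  }
  sub <- advance_mechanics(sub, 50, dt = dt_sub)  # settle
  state$counter <- sub$counter

  # stage 4-5: remove the envelope, instantiate daughters
  mkfinal <- function(sc, id) {
    d <- new_cell_from_ring(sc$xy, mother$type, cfg, id = id,
                            rest = sc$rest, birthA = Am / 2)
    d$Aref <- Am / 2
    d$tau <- cfg$cell$cycle_time *
      max(1 - 3 * cfg$cell$cycle_cv,
          min(1 + 3 * cfg$cell$cycle_cv, 1 + cfg$cell$cycle_cv * rnorm(1)))
    d$polarity <- mother$polarity
    d$secreting <- mother$secreting
    d$constricting <- mother$constricting
    d$Wmul <- mother$Wmul
    d$D <- mother$D
    d$KV <- mother$KV
    if (!is.null(d$polarity)) {
      d <- classify_regions(d)
      if (d$secreting) d$marked[d$region == 1L] <- 1L
    }
    d
  }
  id1 <- state$next_id; id2 <- state$next_id + 1L
  state$next_id <- state$next_id + 2L
  d1 <- mkfinal(sub$cells[[2]], id1)
  d2 <- mkfinal(sub$cells[[3]], id2)
  mid <- mother$id
  state$cells[[idx]] <- d1
  state$cells[[length(state$cells) + 1]] <- d2
  # reassign the mother's intracellular tracers to the nearer daughter
  pown <- state$particles$owner
  if (any(pown == mid)) {
    c1 <- polygon_centroid(d1$xy); c2 <- polygon_centroid(d2$xy)
    for (k in which(pown == mid)) {
      p <- c(state$particles$x[k], state$particles$y[k])
      nearer <- if (sum((p - c1)^2) <= sum((p - c2)^2)) 1 else 2
      tgt <- if (nearer == 1) c1 else c2
      state$particles$owner[k] <- if (nearer == 1) id1 else id2
      state$particles$x[k] <- tgt[1]; state$particles$y[k] <- tgt[2]
    }
  }
  state$particles$origin[state$particles$origin == mid] <- id1
  state <- add_event(state, "division", mid,
                     sprintf("daughters %d,%d mode %s", id1, id2, mode))
  state
}

#' Proliferation-rate controller
#'
#' Enforces the observed per-type cycling fractions: at each invocation
#' the cycling-cell count of every type is driven to an
#' expectation-preserving rounding of `target * N` (floor plus a Bernoulli
#' draw on the fractional part, so the time-averaged realized fraction
#' equals the set-point at any population size, and equals
#' `round(target * N)` exactly whenever `target * N` is an integer).
#' Excess cycling cells are picked uniformly at random and set quiescent;
#' if the cycling count has fallen below the set-point, randomly chosen
#' quiescent cells are re-activated. DCM types and CBM hepatoblasts are
#' controlled separately.
#'
#' @param state A [mech_state()].
#' @param targets Named fractions per type (defaults from the
#'   configuration: cholangiocyte 0.26, hepatoblast 0.107, mesenchyme 0).
#' @return The state with quiescence flags updated.
#' @export
proliferation_controller <- function(state,
                                     targets = state$config$fate$cycling_targets) {
  draw_n <- function(f, N) {
    t <- f * N
    as.integer(floor(t) + (runif(1) < (t - floor(t))))
  }
  types <- vapply(state$cells, `[[`, "", "type")
  for (tp in names(targets)) {
    members <- which(types == tp)
    if (!length(members)) next
    tn <- draw_n(targets[[tp]], length(members))
    q <- vapply(state$cells[members], `[[`, TRUE, "quiescent")
    cyc <- members[!q]
    if (length(cyc) > tn) {
      off <- cyc[sample.int(length(cyc), length(cyc) - tn)]
      for (i in off) state$cells[[i]]$quiescent <- TRUE
    } else if (length(cyc) < tn) {
      qi <- members[q]
      on <- qi[sample.int(length(qi), min(length(qi), tn - length(cyc)))]
      for (i in on) state$cells[[i]]$quiescent <- FALSE
    }
  }
  # CBM hepatoblasts (far field), controlled at the hepatoblast set-point
  if (nrow(state$cbm) && "hepatoblast" %in% names(targets)) {
    hb <- which(state$cbm$type == "hepatoblast" & !state$cbm$fixed)
    if (length(hb)) {
      tn <- draw_n(targets[["hepatoblast"]], length(hb))
      cyc <- hb[!state$cbm$quiescent[hb]]
      if (length(cyc) > tn) {
        state$cbm$quiescent[cyc[sample.int(length(cyc), length(cyc) - tn)]] <- TRUE
      } else if (length(cyc) < tn) {
        qi <- hb[state$cbm$quiescent[hb]]
        if (length(qi)) {
          state$cbm$quiescent[qi[sample.int(length(qi),
                                            min(length(qi), tn - length(cyc)))]] <- FALSE
        }
      }
    }
  }
  state
}

#' Realized cycling fractions by type
#'
#' @param state A [mech_state()].
#' @return Named vector of cycling fractions over the DCM cells of each
#'   type (plus `cbm_hepatoblast` for the far field).
#' @export
cycling_fractions <- function(state) {
  types <- vapply(state$cells, `[[`, "", "type")
  q <- vapply(state$cells, `[[`, TRUE, "quiescent")
  out <- c()
  for (tp in unique(types)) {
    if (tp == "envelope") next
    out[tp] <- mean(!q[types == tp])
  }
  hb <- state$cbm$type == "hepatoblast" & !state$cbm$fixed
  if (any(hb)) out["cbm_hepatoblast"] <- mean(!state$cbm$quiescent[hb])
  out
}

#' Hepatoblast-to-cholangiocyte differentiation
#'
#' A hepatoblast differentiates after its signalling timer (`T_sig` hours)
#' has run down; the timer counts down only while the cell is both in
#' contact with a cholangiocyte and bordering free extracellular space
#' (the duct lumen), and is frozen otherwise. On conversion the cell
#' becomes a cholangiocyte with reference and birth volume scaled by the
#' cholangiocyte size factor (0.75), an apical vector oriented toward the
#' free space, tight junctions, and secretion enabled.
#'
#' @param state A [mech_state()].
#' @param dt Elapsed time (h) since the previous fate update.
#' @param cls Contact classification from `classify_contacts()` (computed
#'   if missing).
#' @param T_sig Signalling time (h).
#' @return The updated state.
#' @export
differentiate_cells <- function(state, dt, cls = NULL,
                                T_sig = state$config$fate$T_sig) {
  if (is.null(cls)) cls <- classify_contacts(state)
  off <- cls$off
  types <- vapply(state$cells, `[[`, "", "type")
  for (ci in which(types == "hepatoblast")) {
    cl <- state$cells[[ci]]
    idx <- (off[ci] + 1):off[ci + 1]
    ep <- cls$elem_partner[idx]
    eg <- cls$elem_gap[idx]
    epd <- ep[ep >= 0]  # DCM partner elements (CBM partners are < 0)
    touching_chol <- length(epd) > 0 &&
      any(types[cls$cellof[epd + 1]] == "cholangiocyte")
    L <- edge_lengths(cl$xy)
    # bordering the (possibly very small) lumen: an open arc, or direct
    # adjacency to the extracellular (particle-rich) luminal space
    free_len <- sum(L[eg > state$config$numerics$gap_open])
    near_lumen <- free_len >= 1
    if (!near_lumen && any(state$particles$owner == 0L)) {
      pp <- state$particles[state$particles$owner == 0L, ]
      dmin <- min(vapply(seq_len(nrow(pp)), function(k) {
        min((cl$xy[, 1] - pp$x[k])^2 + (cl$xy[, 2] - pp$y[k])^2)
      }, 1))
      near_lumen <- dmin < 4  # within 2 um of luminal content
    }
    if (touching_chol && near_lumen) {
      if (is.na(cl$sig_timer)) cl$sig_timer <- T_sig
      cl$sig_timer <- cl$sig_timer - dt
      if (cl$sig_timer <= 0) {
        state$cells[[ci]] <- convert_to_cholangiocyte(cl, eg > state$config$numerics$gap_open,
                                                      state$config)
        state <- seed_secretion(state, cl$id)
        state <- add_event(state, "differentiation", cl$id, "")
        next
      }
    }
    state$cells[[ci]] <- cl
  }
  state
}

# conversion: 0.75x size, polarity toward the free space, secretion and
# constriction competence on, and an apical microlumen dimple (the nascent
# apical pole created by vesicle exocytosis) into which tracer particles
# are excreted
convert_to_cholangiocyte <- function(cell, free, cfg, dir = NULL) {
  f <- cfg$cell$cholangiocyte_size_factor
  cell$type <- "cholangiocyte"
  cell$birthA <- cell$birthA * f
  cell$Aref <- cell$birthA * (1 + cell$age / cell$tau)
  if (is.null(dir)) dir <- largest_free_arc_dir(cell, free)
  if (is.null(dir)) dir <- c(1, 0)
  cell$polarity <- polarity_state(dir, alpha = cfg$polarity$alpha,
                                  gamma_tj = cfg$polarity$gamma_tj)
  cell <- classify_regions(cell)
  cell <- apical_dimple(cell)
  # the exocytosed vesicle content is the initial ion source: the nascent
  # apical pole is osmotically active from the start (marks clear again if
  # the pocket is pressed shut)
  cell$marked[cell$region == 1L] <- 1L
  cell$secreting <- TRUE
  cell$constricting <- TRUE
  # the actomyosin patch assembles with the apical pole; scenarios without
  # apical constriction release it again at the next update
  cell$ac_set <- list(apical = which(cell$region == 1L),
                      tj = which(cell$region == 3L))
  cell$ac_abp <- cell$polarity$abp
  cell <- constrict_elements(cell, cell$ac_set$apical, cell$ac_set$tj,
                             cfg$polarity$constriction[["medioapical"]],
                             cfg$polarity$constriction[["circumferential"]])
  cell$cfac <- rep(1, nrow(cell$xy))
  cell$cfac[cell$ac_set$apical] <-
    cfg$polarity$constriction[["medioapical"]]
  cell$cfac[cell$ac_set$tj] <-
    cfg$polarity$constriction[["circumferential"]]
  cell$sig_timer <- NA_real_
  cell
}

# Retract the apical arc toward the centroid so that the cell instantly
# realizes its post-differentiation volume, the loss concentrated at the
# apical pole (apical water efflux): the vacated crescent is the nascent
# microlumen. The cortex is rebased to the retracted geometry (the
# conversion is a remodeling event), so the pocket does not snap back.
apical_dimple <- function(cell) {
  reg <- cell$region
  apel <- which(reg == 1L)
  if (!length(apel)) return(cell)
  n <- nrow(cell$xy)
  ap <- unique(c(apel, apel %% n + 1L))
  L <- edge_lengths(cell$xy)
  A <- polygon_area(cell$xy)
  dA <- max(0, A - cell$Aref)
  # shallow dish only: a deeper retraction would invaginate the ring onto
  # itself (self-contact is not modeled); the remaining volume difference
  # vents through ordinary volume relaxation
  depth <- min(1.5, dA / max(sum(L[apel]), 1))
  kcoef <- cell$kel[1] * cell$rest[1]  # E_cor h_cor h_z, invariant
  ctr <- polygon_centroid(cell$xy)
  v <- sweep(cell$xy[ap, , drop = FALSE], 2, ctr)
  r <- sqrt(rowSums(v^2))
  cell$xy[ap, ] <- v * pmax(0.3, (r - depth) / r) +
    rep(ctr, each = length(ap))
  cell$rest <- edge_lengths(cell$xy)
  cell$rest0 <- cell$rest
  cell$base_rest <- cell$rest
  cell$kel <- kcoef / cell$rest
  cell$kel0 <- kcoef / cell$base_rest
  cell
}

# --- CBM growth & division (area-equivalent, 2D slab) -------------------
cbm_grow <- function(state, dt) {
  cb <- state$cbm
  act <- !cb$fixed & !cb$quiescent & cb$type == "hepatoblast"
  cb$age[act] <- cb$age[act] + dt
  cb$R[act] <- cb$birthR[act] * sqrt(1 + cb$age[act] / cb$tau[act])
  state$cbm <- cb
  due <- which(act & cb$age >= cb$tau)
  for (j in due) state <- cbm_divide(state, j)
  state
}

cbm_divide <- function(state, j) {
  cb <- state$cbm
  a <- runif(1, 0, pi)
  dxy <- c(cos(a), sin(a)) * 0.6 * cb$birthR[j]
  cv <- state$config$cell$cycle_cv
  mk <- function(sgn, id) {
    r <- cb[j, ]
    r$id <- id
    r$x <- cb$x[j] + sgn * dxy[1]; r$y <- cb$y[j] + sgn * dxy[2]
    r$R <- cb$birthR[j]; r$age <- 0
    r$tau <- state$config$cell$cycle_time *
      max(1 - 3 * cv, min(1 + 3 * cv, 1 + cv * rnorm(1)))
    r
  }
  id1 <- state$next_id; id2 <- state$next_id + 1L
  state$next_id <- state$next_id + 2L
  mid <- cb$id[j]
  state$cbm <- rbind(cb[-j, ], mk(-1, id1), mk(1, id2))
  add_event(state, "cbm_division", mid, sprintf("daughters %d,%d", id1, id2))
}
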