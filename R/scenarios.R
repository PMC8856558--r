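# Experiment families: the idealized cell bilayer (mechanisms I-III) and
# the portal-vein duct system (model variants 0-3), plus the coupled
# simulation loop that interleaves mechanics with polarity, tracer,
# growth/division, differentiation and proliferation control.

#' Model variant switches
#'
#' Variant 0: random division direction, no apical constriction, no
#' osmotic effects. Variant 1: oriented division. Variant 2: oriented
#' division + apical constriction. Variant 3: oriented division + apical
#' constriction + osmosis.
#'
#' @param model Integer 0-3.
#' @return List with `division` (`"random"`/`"oriented"`),
#'   `apical_constriction`, `osmosis`.
#' @export
model_variant <- function(model) {
  stopifnot(model %in% 0:3)
  list(division = if (model == 0) "random" else "oriented",
       apical_constriction = model >= 2,
       osmosis = model >= 3)
}

clampnorm <- function(n, mean, cv, hard) {
  mean * pmax(1 - hard, pmin(1 + hard, 1 + cv * rnorm(n)))
}

#' Build the idealized cell bilayer
#'
#' Two adhering rows of deformable cells embedded in a fluid medium
#' without external resistance. The central cells of the upper layer are
#' "active": polarized with the planar polarity parallel to the layer and
#' the apical vector toward the opposite layer, and - depending on the
#' mechanism - proliferating, apically constricting, or secreting tracer
#' particles.
#'
#' @param cfg Configuration.
#' @param n_per_layer Cells per layer.
#' @param n_active Number of central active cells in the upper layer.
#' @param mechanism `"division"`, `"constriction"` or `"osmosis"`.
#' @param radius Cell radius (um).
#' @param seed Master seed stored in the state.
#' @param relax_s Initial relaxation (s).
#' @return A [mech_state()].
#' @export
build_bilayer <- function(cfg = default_config(), n_per_layer = 10,
                          n_active = 4, mechanism = "division", radius = 10,
                          seed = 1L, relax_s = 120) {
  stopifnot(n_active <= n_per_layer)
  n_nodes <- nodes_for_radius(radius, cfg)
  sx <- 2 * radius * 0.95
  cells <- list()
  id <- 1L
  for (layer in 0:1) {
    for (i in seq_len(n_per_layer)) {
      cen <- c((i - (n_per_layer + 1) / 2) * sx,
               layer * (2 * radius + 0.05))
      cl <- build_cell(cen, radius, n_nodes, "hepatoblast", cfg, id = id)
      cl$quiescent <- TRUE
      cells[[id]] <- cl
      id <- id + 1L
    }
  }
  st <- mech_state(cells, cfg = cfg, seed = seed)
  a0 <- n_per_layer + (n_per_layer - n_active) %/% 2
  active <- a0 + seq_len(n_active)
  # a narrow apical cleft under the active cells only: the pre-existing
  # lumen nucleation space (microlumina from vesicle exocytosis) through
  # which the mechanisms must grow a cavity; its lateral ends are sealed
  # by the adhering inactive interfaces
  for (i in active) st$cells[[i]]$xy[, 2] <- st$cells[[i]]$xy[, 2] + 0.35
  # staggered cycle phases so the dividing cells divide one after another
  phases <- seq(0.96, by = -0.04, length.out = n_active)
  for (k in seq_along(active)) {
    i <- active[k]
    st$cells[[i]]$polarity <- polarity_state(c(0, -1), pcp = c(1, 0),
                                             alpha = cfg$polarity$alpha,
                                             gamma_tj = cfg$polarity$gamma_tj)
    st$cells[[i]] <- classify_regions(st$cells[[i]])
    if (mechanism == "division") {
      # differential proliferation: the polarized cells stay quiescent and
      # define the weak apical interface; the facing cells of the opposite
      # layer proliferate without restriction, dividing in the layer plane
      # (or at random angles in the control)
      j <- i - n_per_layer
      st$cells[[j]]$polarity <- polarity_state(c(0, -1), pcp = c(1, 0),
                                               alpha = cfg$polarity$alpha,
                                               gamma_tj = cfg$polarity$gamma_tj)
      st$cells[[j]] <- classify_regions(st$cells[[j]])
      st$cells[[j]]$quiescent <- FALSE
      st$cells[[j]]$age <- phases[k] * st$cells[[j]]$tau
      st$cells[[j]] <- grow(st$cells[[j]], 0)
    } else if (mechanism == "constriction") {
      st$cells[[i]]$constricting <- TRUE
    } else if (mechanism == "osmosis") {
      st$cells[[i]]$type <- "cholangiocyte"
      st$cells[[i]]$secreting <- TRUE
      # secretion has already begun when the simulation starts
      st <- seed_secretion(st, st$cells[[i]]$id)
    }
  }
  st$active <- vapply(st$cells[active], `[[`, 1L, "id")
  if (relax_s > 0) st <- advance_mechanics(st, relax_s)
  st
}

#' Build the portal-vein duct system
#'
#' Hybrid configuration around the portal vein: a fixed ring of
#' center-based endothelial cells at the portal-vein radius; a ring of
#' mesenchymal cells around it; hepatoblasts beyond. Within the active
#' segment (where the lumen will form) mesenchyme and hepatoblasts are
#' deformable cells; everywhere else, and in the far field, they are
#' center-based. Cell sizes are Gaussian (sd 10% of the mean, truncated at
#' +-30%). One mid-segment hepatoblast adjacent to the mesenchyme is
#' pre-designated to differentiate into the founder cholangiocyte at t =
#' 0: its apical vector points away from the portal-vein centre, its
#' planar polarity (division axis) is tangential, and it is late in its
#' cell cycle so the first oriented division occurs early.
#'
#' @param cfg Configuration.
#' @param seed Master seed stored in the state.
#' @param seg_half Half-opening angle (rad) of the DCM segment.
#' @param relax_s Initial relaxation (s).
#' @return A [mech_state()] with the founder already differentiated.
#' @export
build_duct_system <- function(cfg = default_config(), seed = 1L,
                              seg_half = pi / 3, relax_s = 300) {
  lob <- cfg$lobule
  rE <- cfg$cell$radius_endothelium
  cvr <- cfg$cell$size_cv; hard <- cfg$cell$size_hard_bound
  st <- mech_state(cfg = cfg, seed = seed)

  ring_angles <- function(r, d) {
    n <- max(3L, round(2 * pi * r / d))
    seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  }
  # size-aware tangent packing: neighbouring centers r_i + r_{i+1} apart
  # (rescaled so the ring closes), so sampled-size variability does not
  # over-compress the initial configuration
  ring_pack <- function(r_ring, d_mean, slack = 1.02) {
    n <- max(3L, round(2 * pi * r_ring / (d_mean * slack)))
    rr <- pmax(5, clampnorm(n, d_mean / 2, cvr, hard))
    gap <- rr + c(rr[-1], rr[1])
    ang <- cumsum(c(0, gap[-n])) / sum(gap) * 2 * pi
    list(angle = ang, r = rr)
  }
  in_seg <- function(a) abs(atan2(sin(a), cos(a))) <= seg_half

  # fixed endothelium at the portal-vein radius
  aE <- ring_angles(lob$R_pv, 2 * rE)
  st <- add_cbm_cells(st, lob$R_pv * cos(aE), lob$R_pv * sin(aE),
                      rep(rE, length(aE)), "endothelium", fixed = TRUE)

  # mesenchyme ring (sizes truncated below at the 5-um discretization
  # minimum of build_cell())
  r_mes <- lob$R_pv + rE + lob$d_mes / 2
  pk <- ring_pack(r_mes, lob$d_mes)
  aM <- pk$angle
  rM <- pk$r
  segM <- in_seg(aM)
  st <- add_cbm_cells(st, r_mes * cos(aM[!segM]), r_mes * sin(aM[!segM]),
                      rM[!segM], "mesenchyme", quiescent = TRUE)
  cells <- list()
  for (k in which(segM)) {
    cl <- build_cell(c(r_mes * cos(aM[k]), r_mes * sin(aM[k])), rM[k],
                     nodes_for_radius(rM[k], cfg), "mesenchyme", cfg,
                     id = st$next_id)
    st$next_id <- st$next_id + 1L
    cl$quiescent <- TRUE
    cells[[length(cells) + 1]] <- cl
  }

  # hepatoblast rows: two near rows (DCM inside the segment), far field
  # CBM. Cells are placed at their current (age-grown) size so that the
  # initial configuration is near mechanical reference; the founder (the
  # mid-segment hepatoblast of the inner row) is late in its cycle.
  r1 <- r_mes + lob$d_mes / 2 + lob$d_hep / 2 + 0.5
  rows_near <- c(r1, r1 + lob$d_hep + 1)
  founder_idx <- NA_integer_
  for (row in seq_along(rows_near)) {
    rr <- rows_near[row]
    pk <- ring_pack(rr, lob$d_hep)
    nH <- length(pk$angle)
    age <- runif(nH, 0, 0.5) * cfg$cell$cycle_time
    da <- abs(atan2(sin(pk$angle), cos(pk$angle)))
    if (row == 1) age[which.min(da)] <- 0.9 * cfg$cell$cycle_time
    gfac <- sqrt(1 + age / cfg$cell$cycle_time)
    # re-space by grown size so references match geometry at t = 0
    gap <- pk$r * gfac + c((pk$r * gfac)[-1], (pk$r * gfac)[1])
    aH <- cumsum(c(0, gap[-nH])) / sum(gap) * 2 * pi
    segH <- in_seg(aH)
    st <- add_cbm_cells(st, rr * cos(aH[!segH]), rr * sin(aH[!segH]),
                        pk$r[!segH], "hepatoblast", age = age[!segH])
    for (k in which(segH)) {
      rg <- min(pk$r[k] * gfac[k], 20)
      cl <- build_cell(c(rr * cos(aH[k]), rr * sin(aH[k])), rg,
                       nodes_for_radius(rg, cfg), "hepatoblast", cfg,
                       id = st$next_id)
      st$next_id <- st$next_id + 1L
      cl$age <- age[k]
      cl$birthA <- cl$Aref / (1 + age[k] / cl$tau)
      cells[[length(cells) + 1]] <- cl
      if (row == 1 && k == which.min(da)) founder_idx <- length(cells)
    }
  }
  for (rr in rows_near[2] + lob$d_hep * (1:2)) {
    pk <- ring_pack(rr, lob$d_hep)
    st <- add_cbm_cells(st, rr * cos(pk$angle), rr * sin(pk$angle), pk$r,
                        "hepatoblast")
  }
  st$cells <- cells

  # let the tissue settle under the background pressure before the founder
  # appears, so the volume shed at differentiation opens the nascent lumen
  st <- apply_background_pressure(st, lob$P_b)
  if (relax_s > 0) st <- advance_mechanics(st, relax_s)

  # founder cholangiocyte: late-cycle, apical vector away from the PV
  fc <- st$cells[[founder_idx]]
  ctr <- polygon_centroid(fc$xy)
  fc <- convert_to_cholangiocyte(fc, logical(nrow(fc$xy)), cfg,
                                 dir = ctr / sqrt(sum(ctr^2)))
  st$cells[[founder_idx]] <- fc
  st$founder_id <- fc$id
  st <- seed_secretion(st, fc$id)
  st <- add_event(st, "differentiation", fc$id, "founder")
  st
}

#' Background tissue pressure on the outer hepatoblasts
#'
#' A constant pressure `P_b` acts on the outermost hepatoblasts (top
#' decile by centre radius) in the radial direction toward the portal
#' vein, mimicking the mechanical resistance of the surrounding growing
#' parenchyma. Each boundary cell carries `P_b` x its exposed arc length x
#' slab depth.
#'
#' @param state A [mech_state()] with CBM hepatoblasts.
#' @param P_b Background pressure (Pa).
#' @return The state with the per-cell boundary forces set (also attached
#'   as attribute `"forces"`).
#' @export
apply_background_pressure <- function(state, P_b) {
  cb <- state$cbm
  F <- matrix(0, nrow(cb), 2)
  cb$fx <- 0; cb$fy <- 0
  hb <- which(cb$type == "hepatoblast" & !cb$fixed)
  if (length(hb) && P_b > 0) {
    r <- sqrt(cb$x[hb]^2 + cb$y[hb]^2)
    outer <- hb[r >= stats::quantile(r, 0.9)]
    if (length(outer)) {
      ro <- sqrt(cb$x[outer]^2 + cb$y[outer]^2)
      arc <- 2 * pi * mean(ro) / length(outer)
      f <- p_line(P_b, state$config$dcm$h_z) * arc
      cb$fx[outer] <- -f * cb$x[outer] / ro
      cb$fy[outer] <- -f * cb$y[outer] / ro
      F[outer, 1] <- cb$fx[outer]; F[outer, 2] <- cb$fy[outer]
    }
  }
  state$cbm <- cb
  attr(state, "forces") <- F
  state
}

# ---------------------------------------------------------------------
# coupled simulation loop
# ---------------------------------------------------------------------
crossed <- function(t0, t1, every) floor(t1 / every + 1e-9) > floor(t0 / every + 1e-9)

# rotate the polarity vectors by the least-squares rigid rotation between
# the centred previous and current node positions
rotate_polarity <- function(cell, prev_centred) {
  cur <- sweep(cell$xy, 2, polygon_centroid(cell$xy))
  cr <- sum(prev_centred[, 1] * cur[, 2] - prev_centred[, 2] * cur[, 1])
  dt <- sum(prev_centred[, 1] * cur[, 1] + prev_centred[, 2] * cur[, 2])
  th <- atan2(cr, dt)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cell$polarity$abp <- as.vector(R %*% cell$polarity$abp)
  cell$polarity$pcp <- as.vector(R %*% cell$polarity$pcp)
  cell
}

simulate_state <- function(state, duration, oriented = TRUE, ac = FALSE,
                           osmosis = FALSE, P_L = 0, controller = FALSE,
                           differentiation = FALSE,
                           T_sig = state$config$fate$T_sig,
                           background = FALSE, update_pol = TRUE,
                           measure = TRUE, verbose = FALSE) {
  cfg <- state$config
  nn <- cfg$numerics
  state$P_L <- if (osmosis) P_L else 0
  macro <- nn$update_every
  mh <- macro / 3600
  dt <- stable_dt(state)
  series <- list()
  record <- function(state) {
    lum <- if (measure) measure_lumen(state) else
      list(area = NA_real_, n_cholangiocytes_lining = NA_integer_)
    cyc <- cycling_fractions(state)
    types <- vapply(state$cells, `[[`, "", "type")
    data.frame(time = state$time, area = lum$area,
               n_lining_chol = lum$n_cholangiocytes_lining,
               n_chol = sum(types == "cholangiocyte"),
               n_hep_dcm = sum(types == "hepatoblast"),
               cyc_chol = if ("cholangiocyte" %in% names(cyc)) cyc[["cholangiocyte"]] else NA_real_,
               cyc_hep_dcm = if ("hepatoblast" %in% names(cyc)) cyc[["hepatoblast"]] else NA_real_,
               cyc_hep_cbm = if ("cbm_hepatoblast" %in% names(cyc)) cyc[["cbm_hepatoblast"]] else NA_real_,
               n_marked = sum(vapply(state$cells, function(cl) sum(cl$marked), 1)),
               n_tp = nrow(state$particles),
               n_extr = sum(state$particles$owner == 0L))
  }
  if (controller) state <- proliferation_controller(state)
  series[[1]] <- record(state)
  t_end <- duration
  while (state$time < t_end - 1e-9) {
    t0 <- state$time
    prev <- lapply(state$cells, function(cl) {
      if (is.null(cl$polarity)) NULL else
        sweep(cl$xy, 2, polygon_centroid(cl$xy))
    })
    state <- advance_mechanics(state, macro, dt)
    state$time <- t0 + mh
    cls <- classify_contacts(state)
    off <- cls$off
    # polarity, regions, constriction
    for (ci in seq_along(state$cells)) {
      cl <- state$cells[[ci]]
      if (is.null(cl$polarity)) next
      if (update_pol) {
        # polarity relaxes toward the lumen-facing surface: the marked
        # (osmotically active) arc when one exists, otherwise the largest
        # open arc
        free <- if (any(cl$marked == 1L)) cl$marked == 1L else
          cls$elem_gap[(off[ci] + 1):off[ci + 1]] > cfg$numerics$gap_open
        cl <- update_polarity(cl, free, mh, cfg$polarity$tau_pol)
      } else if (!is.null(prev[[ci]]) && nrow(prev[[ci]]) == nrow(cl$xy)) {
        # construction-defined polarity co-rotates with the cell body
        # (rigid-body rotation fit); shape changes do not re-aim it
        cl <- rotate_polarity(cl, prev[[ci]])
      }
      # surface identity (apical membrane composition) is material: labels
      # are re-derived from the cones only when the apical-basal axis has
      # rotated substantially since they were assigned
      redo_reg <- is.null(cl$reg_abp) ||
        sum(cl$polarity$abp * cl$reg_abp) < cos(pi / 8)
      if (redo_reg) {
        cl <- classify_regions(cl)
        cl$reg_abp <- cl$polarity$abp
      }
      if (ac && isTRUE(cl$constricting)) {
        # the actomyosin patch is material: the constricted element set is
        # fixed when constriction starts and only re-derived if the
        # apical-basal axis has rotated substantially since
        redo <- is.null(cl$ac_set) ||
          sum(cl$polarity$abp * cl$ac_abp) < cos(pi / 3)
        if (redo) {
          cl$ac_set <- list(apical = which(cl$region == 1L),
                            tj = which(cl$region == 3L))
          cl$ac_abp <- cl$polarity$abp
        }
        # the viscoelastic cortex remodels toward length x factor, so the
        # patch maintains its contraction as a persistent strain offset
        cl$cfac <- rep(1, nrow(cl$xy))
        cl$cfac[cl$ac_set$apical] <-
          cfg$polarity$constriction[["medioapical"]]
        cl$cfac[cl$ac_set$tj] <-
          cfg$polarity$constriction[["circumferential"]]
      } else {
        cl$cfac <- rep(1, nrow(cl$xy))
      }
      state$cells[[ci]] <- cl
    }
    # growth and division
    for (ci in seq_along(state$cells)) {
      state$cells[[ci]] <- grow(state$cells[[ci]], mh)
    }
    repeat {
      due <- which(vapply(state$cells, ready_to_divide, TRUE))
      if (!length(due)) break
      ci <- due[1]
      mode <- if (oriented && !is.null(state$cells[[ci]]$polarity)) {
        "along_pcp"
      } else "random"
      state <- divide_cell(state, ci, mode)
    }
    if (nrow(state$cbm)) state <- cbm_grow(state, mh)
    if (differentiation || osmosis) {
      # one classification pass shared by fate and mark refresh (stale by
      # at most the conversions of this step)
      cls2 <- classify_contacts(state)
      if (differentiation) {
        state <- differentiate_cells(state, mh, cls2, T_sig)
      }
      if (osmosis) {
        state <- secrete(state, mh)
        state <- remark_lumen(state, cls2)
      }
    }
    if (controller && crossed(t0, state$time, nn$controller_every)) {
      state <- proliferation_controller(state)
    }
    if (background) {
      state <- apply_background_pressure(state, cfg$lobule$P_b)
    }
    if (crossed(t0, state$time, nn$measure_every)) {
      series[[length(series) + 1]] <- record(state)
      if (verbose) {
        s <- series[[length(series)]]
        message(sprintf("t = %5.2f h  area = %7.1f um^2  chol = %d",
                        s$time, s$area, s$n_chol))
      }
    }
  }
  state$series <- do.call(rbind, series)
  state
}

#' Run a portal-vein duct simulation
#'
#' Builds the duct system and runs the full coupled loop (mechanics,
#' polarity, tracer osmosis, growth/oriented division, differentiation,
#' proliferation-rate control, background pressure) for the requested
#' model variant. Deterministic for a given seed.
#'
#' @param model Model variant 0-3 (see [model_variant()]).
#' @param cfg Configuration.
#' @param seed Seed of this realization.
#' @param duration Simulated hours after the founder cholangiocyte
#'   appears.
#' @param P_L Lumen (osmotic) pressure in Pa, used by variant 3.
#' @param T_sig Cell-to-cell signalling time (h).
#' @param seg_half Half-opening angle (rad) of the deformable segment.
#' @param measure Measure the lumen at the measurement cadence? (Cycling
#'   statistics do not require it.)
#' @param verbose Print progress?
#' @return The final [mech_state()] with `$series` (time, lumen area,
#'   cell counts, cycling fractions) and `$events`.
#' @export
run_model <- function(model = 3, cfg = default_config(), seed = 1,
                      duration = 24, P_L = cfg$lobule$P_L,
                      T_sig = cfg$fate$T_sig, seg_half = pi / 3,
                      measure = TRUE, verbose = FALSE) {
  v <- model_variant(model)
  set.seed(seed)
  state <- build_duct_system(cfg, seed = seed, seg_half = seg_half)
  simulate_state(state, duration, oriented = v$division == "oriented",
                 ac = v$apical_constriction, osmosis = v$osmosis,
                 P_L = P_L, controller = TRUE, differentiation = TRUE,
                 T_sig = T_sig, background = TRUE, measure = measure,
                 verbose = verbose)
}

#' Run an idealized bilayer simulation
#'
#' @param mechanism `"division"`, `"constriction"` or `"osmosis"`.
#' @param cfg Configuration.
#' @param seed Seed.
#' @param duration Simulated hours.
#' @param division_mode `"along_pcp"` (oriented) or `"random"`; used by
#'   the division mechanism.
#' @param P_L Lumen pressure (Pa) for the osmosis mechanism.
#' @param n_per_layer,n_active Bilayer geometry.
#' @param verbose Print progress?
#' @return The final [mech_state()] with `$series`.
#' @export
run_bilayer <- function(mechanism = "division", cfg = default_config(),
                        seed = 1, duration = 6,
                        division_mode = c("along_pcp", "random"),
                        P_L = cfg$lobule$P_L, n_per_layer = 10,
                        n_active = 4, verbose = FALSE) {
  division_mode <- match.arg(division_mode)
  set.seed(seed)
  # constriction and secretion act from t = 0, while the nucleation cleft
  # is still open; the division runs start from a settled bilayer
  state <- build_bilayer(cfg, n_per_layer, n_active, mechanism, seed = seed,
                         relax_s = if (mechanism == "division") 120 else 0)
  # active-cell polarity is defined by the bilayer construction (apical
  # vector toward the opposite layer) and is not relaxed toward free space
  simulate_state(state, duration,
                 oriented = division_mode == "along_pcp",
                 ac = mechanism == "constriction",
                 osmosis = mechanism == "osmosis", P_L = P_L,
                 controller = FALSE, differentiation = FALSE,
                 background = FALSE, update_pol = FALSE, verbose = verbose)
}
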