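# Internal unit system: length um, time s, force nN. The 2D cross-section
# represents a slab of depth h_z = 10 um (one cell diameter); all areal
# quantities (adhesion energy, friction, pressure, cortex modulus) are
# folded into per-unit-contact-length coefficients here, once.

# Pa -> nN/um^2
pa2int <- function(p) p * 1e-3
# J/m^2 (adhesion energy) -> nN per um of contact length (x slab depth)
w_line <- function(w, h_z = 10) w * 1000 * h_z
# Ns/m^3 (area-specific friction) -> nN s/um per um of contact length:
# the slab depth is folded in, so node drag = gamma2int(g) * l0n
gamma2int <- function(g, h_z = 10) g * 1e-9 * h_z
# m^2/s -> um^2/s
d2int <- function(d) d * 1e12
# Pa (pressure) -> nN per um of loaded boundary length (x slab depth)
p_line <- function(p, h_z = 10) p * 1e-3 * h_z

# per-side adhesion line energy for a region label
# labels: 0 lateral, 1 apical, 2 basal, 3 tight junction
w_side_line <- function(region, cfg) {
  d <- cfg$dcm
  w <- ifelse(region == 1L, d$W_ap,
         ifelse(region == 3L, d$W * d$W_tj_factor, d$W))
  w_line(w, d$h_z)
}

# Default density-correction multiplier for the modified JKR law, over
# relative overlap delta/R*. Regenerate with calibrate_cbm_contact(); the
# values come from pressing a DCM cell pair and comparing the measured
# force-overlap curve with the plain JKR prediction (stiffening at high
# overlap, where the plain law underestimates contact forces).
jkr_mult_default <- function() {
  list(x = c(0.050, 0.310, 1.257, 1.655, 1.887, 2.031),
       y = c(1.000, 1.339, 1.062, 1.007, 1.011, 1.076))
}

# Assemble the C++ parameter list (internal units) from a configuration.
internal_params <- function(cfg, dt = NA_real_, P_L = 0, seed = 1,
                            counter = 0) {
  d <- cfg$dcm
  nn <- cfg$numerics
  jm <- jkr_mult_default()
  list(
    dt = dt,
    g_ext = gamma2int(d$gamma_ext),
    g_free = gamma2int(max(d$gamma_ECM, d$gamma_liq)),
    g_int = gamma2int(d$gamma_int),
    g_cbm = gamma2int(d$gamma_ECM),
    h_int = d$h_int,
    k_rep = d$k_rep,
    PL = p_line(P_L, d$h_z),
    Dtp = d2int(cfg$tracer$D_tp),
    r_cap = cfg$tracer$r_cap,
    skin = nn$skin,
    domR = nn$domain_radius,
    maxdisp = nn$maxdisp,
    cbm_tol = nn$cbm_tol,
    gap_open = nn$gap_open,
    gap_close = nn$gap_close,
    tau_ve = d$tau_ve,
    kcoef = pa2int(d$E_cor) * (d$h_cor * 1e-3) * d$h_z,
    tp_every = as.integer(nn$tp_every),
    cbm_iters = as.integer(nn$cbm_iters),
    jx = jm$x, jy = jm$y,
    seed = as.double(seed),
    counter = as.double(counter)
  )
}

#' Stable explicit timestep for a state
#'
#' The integrator is explicit Euler on an overdamped balance, so the
#' timestep is bounded by friction/stiffness ratios. Two bounds matter:
#' free-surface nodes (lowest drag) against the in-plane cortex stiffness,
#' and in-contact nodes (cell-cell drag) against the cohesive-zone
#' stiffness. The returned step is `dt_safety` times the smaller bound,
#' capped at `dt_cap`.
#'
#' @param state A [mech_state()].
#' @return Timestep in seconds.
#' @export
stable_dt <- function(state) {
  cfg <- state$config
  d <- cfg$dcm
  g_free <- gamma2int(max(d$gamma_ECM, d$gamma_liq))
  g_ext <- gamma2int(d$gamma_ext)
  bound <- cfg$numerics$dt_cap
  for (cl in state$cells) {
    l0 <- cl$rest
    l0n <- (l0 + l0[c(length(l0), seq_len(length(l0) - 1))]) / 2
    kint <- 2 * max(cl$kel) + 8 * cl$kb / min(l0n)^2 +
      cl$KV * max(l0n)^2 / cl$Aref
    b1 <- g_free * min(l0n) / kint
    # contact stiffness: repulsion slope plus adhesive ramp slope
    t0 <- w_line(d$W * d$W_tj_factor, d$h_z) / (1.5 * d$h_int)
    kcon <- (d$k_rep + t0 / (0.5 * d$h_int)) * max(l0n)
    b2 <- g_ext * min(l0n) / kcon
    bound <- min(bound, cfg$numerics$dt_safety * min(b1, b2))
  }
  bound
}
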