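# Configuration: every physical symbol of the model in its printed unit
# (Pa, J/m^2, Ns/m^3, m^2/s, um, h), plus numerical controls. The
# conversion layer to internal simulation units (um, s, nN) lives in
# units.R; nothing outside that file converts units.

#' Default simulation configuration
#'
#' Returns the nominal parameter set of the model: cortex elasticity and
#' thickness, bulk modulus, adhesion energies, friction coefficients,
#' motility, cycle time, CBM elastic constants, lobule geometry and
#' pressures, polarity-cone angles, constriction factors, tracer-particle
#' kinetics, fate-control set-points and numerical controls.
#'
#' Units follow the conventional presentation of these quantities:
#' pressures and moduli in Pa, adhesion energies in J/m^2, friction in
#' Ns/m^3, motility in m^2/s, lengths in micrometres, times in hours.
#'
#' @return A nested named list; see `vignette("lumenogenesis")` for the
#'   meaning and provenance of each group.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$dcm$W            # global cell-cell adhesion energy, J/m^2
#' cfg$lobule$P_b       # tissue background pressure, Pa
default_config <- function() {
  list(
    cell = list(
      radius_hepatoblast = 7.5,   # um (d_hep = 15 um)
      radius_mesenchyme  = 5.0,   # um (d_mes = 10 um)
      radius_endothelium = 5.0,   # um
      size_cv = 0.10,             # Gaussian sd as fraction of mean size
      size_hard_bound = 0.30,     # truncation of the size distribution
      cycle_time = 24,            # h
      cycle_cv = 0.10,
      cholangiocyte_size_factor = 0.75
    ),
    dcm = list(
      E_cor = 1000,      # Pa, cortex Young's modulus
      h_cor = 500,       # nm, cortex thickness
      nu_cor = 0.5,      # cortex Poisson ratio
      K_V = 1500,        # Pa, cell bulk modulus (plausible range 750-2500)
      W = 9e-4,          # J/m^2, global cell-cell adhesion energy
      W_ap = 1e-6,       # J/m^2, apical adhesion energy
      W_tj_factor = 10,  # tight-junction adhesion = W_tj_factor * W
      gamma_int = 1e-4,  # Ns/m^3, nodal friction
      gamma_ext = 5e10,  # Ns/m^3, cell-cell friction
      gamma_ECM = 1e8,   # Ns/m^3, cell-ECM friction
      gamma_liq = 500,   # Ns/m^3, cell-liquid friction
      D = 1e-16,         # m^2/s, cell motility
      n_nodes = 60,      # ring nodes for a 10-um-radius cell (scaled by R)
      tau_ve = 600,      # s, cortical turnover (rest-length remodeling) time
      h_int = 0.4,       # um, cohesive-zone interaction range
      k_rep = 300,       # nN/um^2 per um contact length, repulsion stiffness
      h_z = 10           # um, slab depth of the 2D cross-section
    ),
    cbm = list(
      E = 450,           # Pa
      nu = 0.47,
      D = 1e-16          # m^2/s
    ),
    polarity = list(
      alpha = pi / 4,        # rad, apical/basal cone half-angle
      gamma_tj = pi / 12,    # rad, tight-junction belt width
      tau_pol = 0.5,         # h, apical-vector relaxation time
      constriction = c(circumferential = 0.6, medioapical = 0.8)
    ),
    tracer = list(
      rate = 300,         # particles/h per secreting cell
      D_tp = 1e-11,       # m^2/s
      r_cap = 1.2,        # um, surface-marking capture radius
      max_per_cell = 80   # live-particle cap per secreting cell
    ),
    lobule = list(
      R_pv = 50,          # um, portal-vein radius
      P_L = 50,           # Pa, lumen (osmotic) pressure
      P_b = 50,           # Pa, tissue background pressure
      d_mes = 10,         # um, mean mesenchymal cell diameter
      d_hep = 15          # um, mean hepatoblast diameter
    ),
    fate = list(
      T_sig = 2,          # h, cholangiocyte->hepatoblast signalling time
      cycling_targets = c(cholangiocyte = 0.26, hepatoblast = 0.107,
                          mesenchyme = 0)
    ),
    numerics = list(
      dt_cap = 0.5,         # s, hard timestep cap
      dt_safety = 0.3,      # fraction of the stability bound
      update_every = 60,    # s, cadence of the event layer (growth, fate, ...)
      controller_every = 0.5, # h, proliferation-controller cadence
      measure_every = 0.25, # h, measurement cadence
      skin = 2.0,           # um, neighbour-list skin
      tp_every = 15,        # tracer substep stride
      maxdisp = 0.1,        # um, per-substep displacement clamp (< h_int/4)
      gap_open = 0.15,      # um, gap above which a surface counts as open
      gap_close = 0.08,     # um, gap below which a mark is cleared
      cbm_iters = 60,
      cbm_tol = 1e-8,
      domain_radius = 400   # um, tracer retirement radius
    )
  )
}

#' Load a simulation configuration from a YAML file
#'
#' Reads a YAML file of (possibly partial) overrides and merges it into
#' [default_config()]. Unknown keys are rejected; basic physical validity
#' is enforced (`validate_config()`).
#'
#' @param path Path to a YAML file. Top-level and nested keys must match
#'   the names in [default_config()].
#' @return A full configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ov <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_cfg <- function(base, over, where) {
    for (k in names(over)) {
      if (!k %in% names(base)) {
        stop("unknown configuration key: ", paste0(where, k))
      }
      if (is.list(base[[k]]) && is.list(over[[k]])) {
        base[[k]] <- merge_cfg(base[[k]], over[[k]], paste0(where, k, "$"))
      } else {
        v <- over[[k]]
        if (!is.null(names(base[[k]])) && is.list(v)) v <- unlist(v)
        if (!is.null(names(base[[k]]))) {
          bad <- setdiff(names(v), names(base[[k]]))
          if (length(bad)) {
            stop("unknown configuration key: ", paste0(where, k, "$", bad[1]))
          }
          base[[k]][names(v)] <- v
        } else {
          base[[k]] <- v
        }
      }
    }
    base
  }
  cfg <- merge_cfg(cfg, ov, "")
  validate_config(cfg)
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Validate a configuration
#'
#' Checks required keys, signs and plausible ranges. Out-of-range but
#' physically meaningful values (for example a bulk modulus outside the
#' plausible 750-2500 Pa window) give a warning rather than an error.
#'
#' @param cfg Configuration list.
#' @return `cfg`, invisibly; errors/warnings on problems.
#' @export
validate_config <- function(cfg) {
  need <- c("cell", "dcm", "cbm", "polarity", "tracer", "lobule", "fate",
            "numerics")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("missing required configuration section: ", miss[1])
  if (cfg$lobule$P_L < 0) stop("P_L must be >= 0")
  if (cfg$lobule$P_b < 0) stop("P_b must be >= 0")
  if (cfg$dcm$W <= 0 || cfg$dcm$W_ap <= 0) stop("adhesion energies must be > 0")
  for (g in c("gamma_int", "gamma_ext", "gamma_ECM", "gamma_liq")) {
    if (cfg$dcm[[g]] < 0) stop(g, " must be >= 0")
  }
  co <- cfg$polarity$constriction
  if (any(co <= 0) || any(co > 1)) {
    stop("constriction factors must be in (0, 1]")
  }
  if (cfg$cell$cycle_time <= 0) stop("cycle_time must be > 0")
  if (any(cfg$fate$cycling_targets < 0) || any(cfg$fate$cycling_targets > 1)) {
    stop("cycling targets must be in [0, 1]")
  }
  if (cfg$dcm$h_z != 10) stop("the slab depth h_z is fixed at 10 um")
  if (cfg$dcm$K_V < 750 || cfg$dcm$K_V > 2500) {
    warning("K_V = ", cfg$dcm$K_V, " Pa is outside the plausible 750-2500 Pa range")
  }
  invisible(cfg)
}
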