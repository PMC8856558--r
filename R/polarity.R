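# Apico-basal (ABP) and planar (PCP) polarity, surface-region
# classification (apical cone, basal cone, tight-junction belt),
# region-dependent adhesion and apical constriction.

region_codes <- c(lateral = 0L, apical = 1L, basal = 2L, tight_junction = 3L)

#' Create a polarity state
#'
#' @param abp Apical-basal unit vector (apical direction).
#' @param pcp Planar polarity unit vector; default: perpendicular to
#'   `abp`.
#' @param alpha Apical/basal cone half-angle (rad).
#' @param gamma_tj Tight-junction belt angular width (rad).
#' @return A `polarity_state` list.
#' @export
polarity_state <- function(abp, pcp = NULL, alpha = pi / 5,
                           gamma_tj = pi / 12) {
  abp <- abp / sqrt(sum(abp^2))
  if (is.null(pcp)) pcp <- c(-abp[2], abp[1])
  pcp <- pcp - sum(pcp * abp) * abp
  pcp <- pcp / sqrt(sum(pcp^2))
  stopifnot(alpha > 0, alpha < pi / 2, gamma_tj >= 0)
  structure(list(abp = abp, pcp = pcp, alpha = alpha, gamma_tj = gamma_tj),
            class = "polarity_state")
}

#' Classify the surface regions of a cell
#'
#' Labels every ring element by the angle between its midpoint direction
#' (from the cell centroid) and the apical-basal vector: apical within the
#' cone half-angle `alpha` of the ABP vector, tight junction within
#' `[alpha, alpha + gamma_tj]`, basal within `alpha` of the anti-apical
#' direction, lateral otherwise. Unpolarized cells are entirely lateral.
#'
#' @param cell A [build_cell()] object (with or without `$polarity`).
#' @return The cell with `$region` updated (0 lateral, 1 apical, 2 basal,
#'   3 tight junction).
#' @export
classify_regions <- function(cell) {
  n <- nrow(cell$xy)
  if (is.null(cell$polarity)) {
    cell$region <- integer(n)
    return(cell)
  }
  p <- cell$polarity
  ctr <- polygon_centroid(cell$xy)
  nx <- c(2:n, 1)
  mid <- (cell$xy + cell$xy[nx, , drop = FALSE]) / 2
  dx <- mid[, 1] - ctr[1]; dy <- mid[, 2] - ctr[2]
  nr <- sqrt(dx^2 + dy^2)
  cosang <- pmin(1, pmax(-1, (dx * p$abp[1] + dy * p$abp[2]) / nr))
  ang <- acos(cosang)  # angle to the apical direction, in [0, pi]
  reg <- integer(n)
  reg[ang <= p$alpha] <- region_codes[["apical"]]
  reg[ang > p$alpha & ang <= p$alpha + p$gamma_tj] <-
    region_codes[["tight_junction"]]
  reg[ang >= pi - p$alpha] <- region_codes[["basal"]]
  cell$region <- reg
  cell
}

#' Apply apical constriction to a cell
#'
#' Reduces the equilibrium (rest) lengths of the apical-domain elements by
#' the medioapical factor and of the tight-junction belt elements by the
#' circumferential factor; the basal surface is untouched. The nodes then
#' move toward each other until a new mechanical equilibrium is reached
#' under the normal dynamics.
#'
#' @param cell A polarized, region-classified cell.
#' @param factors Named or positional numeric pair
#'   `(circumferential, medioapical)`, both in (0, 1].
#' @return The cell with mutated rest lengths.
#' @export
apply_constriction <- function(cell,
                               factors = c(circumferential = 0.6,
                                           medioapical = 0.8)) {
  if (any(factors <= 0) || any(factors > 1)) {
    stop("constriction factors must be in (0, 1]")
  }
  circ <- factors[[1]]; medio <- factors[[2]]
  ap <- which(cell$region == region_codes[["apical"]])
  tj <- which(cell$region == region_codes[["tight_junction"]])
  constrict_elements(cell, ap, tj, medio, circ)
}

# contract a material set of elements: shorter equilibrium length of the
# same cortex material, hence proportionally stiffer springs
# (kel = E_cor h_cor h_z / rest throughout)
constrict_elements <- function(cell, apical_idx, tj_idx, medio, circ) {
  rest <- cell$base_rest
  rest[apical_idx] <- rest[apical_idx] * medio
  rest[tj_idx] <- rest[tj_idx] * circ
  cell$rest <- rest
  cell$kel <- cell$kel0 * cell$base_rest / rest
  cell
}

#' Effective adhesion energy between two surface elements
#'
#' Cadherin binding is homophilic, so the pairwise work of separation is
#' limited by the sparser side: the minimum of the per-side energies
#' (apical side: `W_ap`, almost no cadherins; tight-junction side:
#' `W_tj_factor * W`; basal/lateral: `W`). Symmetric in its arguments.
#' Apical-apical pairs give `W_ap`, tight-junction pairs
#' `W_tj_factor * W`, basal/lateral pairs `W`.
#'
#' @param label_a,label_b Region labels: `"lateral"`, `"apical"`,
#'   `"basal"`, `"tight_junction"` (or integer codes 0-3).
#' @param cfg Configuration.
#' @return Effective adhesion energy in J/m^2.
#' @export
effective_adhesion <- function(label_a, label_b, cfg = default_config()) {
  tolab <- function(l) {
    if (is.character(l)) region_codes[[l]] else as.integer(l)
  }
  wside <- function(code) {
    d <- cfg$dcm
    if (code == region_codes[["apical"]]) d$W_ap
    else if (code == region_codes[["tight_junction"]]) d$W * d$W_tj_factor
    else d$W
  }
  min(wside(tolab(label_a)), wside(tolab(label_b)))
}

largest_free_arc_dir <- function(cell, free) {
  n <- nrow(cell$xy)
  if (!any(free)) return(NULL)
  nx <- c(2:n, 1)
  ev <- cell$xy[nx, , drop = FALSE] - cell$xy
  L <- sqrt(ev[, 1]^2 + ev[, 2]^2)
  # contiguous free runs on the ring (with wrap-around)
  r <- rle(free)
  runs <- data.frame(val = r$values, len = r$lengths)
  idx <- split(seq_len(n), rep(seq_len(nrow(runs)), r$lengths))
  if (nrow(runs) > 1 && runs$val[1] && runs$val[nrow(runs)]) {
    idx[[1]] <- c(idx[[length(idx)]], idx[[1]])
    runs$val[nrow(runs)] <- FALSE
  }
  freeruns <- which(runs$val)
  if (!length(freeruns)) return(NULL)
  arclen <- vapply(freeruns, function(k) sum(L[idx[[k]]]), 1)
  best <- idx[[freeruns[which.max(arclen)]]]
  # length-weighted mean outward normal of the arc
  ox <- sum(ev[best, 2]); oy <- -sum(ev[best, 1])
  nr <- sqrt(ox^2 + oy^2)
  if (nr < 1e-9) return(NULL)
  c(ox, oy) / nr
}

#' Update the polarity of a cell from its contact context
#'
#' The apical-basal vector relaxes toward the outward direction of the
#' cell's largest free (lumen- or medium-facing) surface arc, with the
#' rotation per call capped; the planar polarity vector is
#' re-orthogonalized, keeping its handedness. Fully surrounded cells keep
#' their polarity unchanged.
#'
#' @param cell A polarized cell.
#' @param free Logical per-element vector: element faces free space.
#' @param dt Elapsed time (h) represented by this update.
#' @param tau_pol Polarity relaxation time constant (h).
#' @return The cell with updated `$polarity`.
#' @export
update_polarity <- function(cell, free, dt = 1 / 6, tau_pol = 0.5) {
  if (is.null(cell$polarity)) return(cell)
  tgt <- largest_free_arc_dir(cell, as.logical(free))
  if (is.null(tgt)) return(cell)
  p <- cell$polarity
  a0 <- atan2(p$abp[2], p$abp[1])
  a1 <- atan2(tgt[2], tgt[1])
  dlt <- atan2(sin(a1 - a0), cos(a1 - a0))
  rot <- dlt * min(1, dt / tau_pol)
  abp <- c(cos(a0 + rot), sin(a0 + rot))
  pcp <- c(-abp[2], abp[1])
  if (sum(pcp * p$pcp) < 0) pcp <- -pcp
  cell$polarity$abp <- abp
  cell$polarity$pcp <- pcp
  cell
}
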