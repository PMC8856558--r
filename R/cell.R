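# Deformable cells: closed counter-clockwise node rings with viscoelastic
# edge elements, a reference (slab) volume and per-cell mechanical
# parameters in internal units.

polygon_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2
}

polygon_centroid <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  cr <- xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((xy[, 1] + xy[j, 1]) * cr), sum((xy[, 2] + xy[j, 2]) * cr)) / (6 * a)
}

edge_lengths <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  sqrt((xy[j, 1] - xy[, 1])^2 + (xy[j, 2] - xy[, 2])^2)
}

#' Build a deformable cell
#'
#' Discretizes a cell of the given radius as a regular polygon ring of
#' cortex nodes. Edge elements get their rest length from the initial
#' geometry and their stiffness from the cortex modulus, thickness and the
#' slab depth; the enclosed polygon area becomes the reference volume.
#'
#' @param center Numeric length-2, cell center (um).
#' @param radius Cell radius in um; must lie in `[5, 20]`.
#' @param n_nodes Number of ring nodes (>= 12).
#' @param cell_type One of `"hepatoblast"`, `"cholangiocyte"`,
#'   `"mesenchyme"`, `"endothelium"`, `"envelope"`.
#' @param cfg Configuration, see [default_config()].
#' @param id Integer cell id (assigned by the caller/state).
#' @return An object of class `dcm_cell`.
#' @export
#' @examples
#' cl <- build_cell(c(0, 0), 10, 60, "hepatoblast")
#' abs(cl$Aref - pi * 100) / (pi * 100) # < 0.5%: regular-polygon area deficit
build_cell <- function(center, radius, n_nodes, cell_type = "hepatoblast",
                       cfg = default_config(), id = 1L) {
  if (n_nodes < 12) {
    stop("discretization error: a cell ring needs at least 12 nodes")
  }
  if (radius < 5 || radius > 20) {
    stop("cell radius must be in [5, 20] um")
  }
  th <- seq(0, 2 * pi, length.out = n_nodes + 1)[-(n_nodes + 1)]
  xy <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
  new_cell_from_ring(xy, cell_type, cfg, id = id)
}

# Build a dcm_cell from an arbitrary CCW ring (also used for scripted
# fixtures and daughter cells). rest defaults to current edge lengths.
new_cell_from_ring <- function(xy, cell_type, cfg, id = 1L, rest = NULL,
                               tau = NULL, birthA = NULL, allow_cw = FALSE) {
  if (!allow_cw && polygon_area(xy) <= 0) {
    stop("degenerate geometry: cell ring must be counter-clockwise with positive area")
  }
  d <- cfg$dcm
  n <- nrow(xy)
  if (is.null(rest)) rest <- edge_lengths(xy)
  # cortex sheet stiffness E_cor * h_cor over the slab depth
  kel <- pa2int(d$E_cor) * (d$h_cor * 1e-3) * d$h_z / rest
  kb <- pa2int(d$E_cor) * (d$h_cor * 1e-3)^3 / 12 * d$h_z / mean(rest)
  A <- polygon_area(xy)
  if (is.null(tau)) tau <- cfg$cell$cycle_time
  structure(list(
    id = as.integer(id),
    type = cell_type,
    xy = xy,
    rest = rest,
    rest0 = rest,
    base_rest = rest,
    kel = kel,
    kel0 = kel,
    kb = kb,
    th0 = 2 * pi / n,
    Aref = A,
    birthA = if (is.null(birthA)) A else birthA,
    KV = p_line(d$K_V, d$h_z),
    Wmul = if (identical(cell_type, "envelope")) 1e-6 else 1,
    D = d2int(d$D),
    fixed = identical(cell_type, "envelope"),
    polarity = NULL,
    region = integer(n),
    marked = integer(n),
    quiescent = FALSE,
    tau = tau,
    age = 0,
    sig_timer = NA_real_,
    secreting = FALSE,
    constricting = FALSE,
    cfac = rep(1, n),
    fext = c(0, 0)
  ), class = "dcm_cell")
}

#' @export
print.dcm_cell <- function(x, ...) {
  cat(sprintf("<dcm_cell %d: %s, %d nodes, A = %.1f um^2 (ref %.1f)%s>\n",
              x$id, x$type, nrow(x$xy), polygon_area(x$xy), x$Aref,
              if (is.null(x$polarity)) "" else ", polarized"))
  invisible(x)
}

cell_radius_eff <- function(cell) sqrt(max(polygon_area(cell$xy), 1e-9) / pi)

# node count for a cell of radius R given the reference density
nodes_for_radius <- function(radius, cfg) {
  max(24L, as.integer(round(cfg$dcm$n_nodes * radius / 10)))
}
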