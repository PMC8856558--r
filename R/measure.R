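# Quantification: lumen area by tracing the free boundary polygon of the
# largest apical-adjacent extracellular cavity, apical/basal arc lengths,
# and ensemble statistics over stochastic realizations.

#' Measure the lumen of a state
#'
#' Finds enclosed extracellular cavities by walking the free (non-contact)
#' surface elements of the cell rings: free stretches are traced along the
#' ring; where a ring enters a cell-cell contact the walk jumps to the
#' contact partner and continues on the neighbouring cell, so the traced
#' polygon closes around the cavity. The lumen is the largest such cavity
#' adjacent to at least one apical element; its area comes from the
#' shoelace formula. Satellite micro-gaps below `min_area` are ignored;
#' confluent tissue yields area 0.
#'
#' @param state A [mech_state()].
#' @param min_area Smallest cavity area (um^2) considered.
#' @param neck Fallback measurement closure radii (um): if no enclosed
#'   cavity is found at the physical interaction range, passages narrower
#'   than these are progressively closed, so a lumen that transiently
#'   leaks through a sub-cell-scale neck keeps a well-defined boundary.
#' @return A `lumen_record` list: `time` (h), `area` (um^2),
#'   `boundary_cells` (ids), `n_cholangiocytes_lining`, `polygon`.
#' @export
measure_lumen <- function(state, min_area = 1, neck = c(0.8, 1.2)) {
  cav <- trace_cavities(state, classify_contacts(state), min_area)
  for (r in neck) {
    if (length(cav)) break
    cav <- trace_cavities(state, classify_contacts(state, h_int = r),
                          min_area)
  }
  if (!length(cav)) {
    return(structure(list(time = state$time, area = 0,
                          boundary_cells = integer(),
                          n_cholangiocytes_lining = 0L, polygon = NULL),
                     class = "lumen_record"))
  }
  areas <- vapply(cav, `[[`, 1, "area")
  best <- cav[[which.max(areas)]]
  types <- vapply(state$cells, `[[`, "", "type")
  ids <- vapply(state$cells, `[[`, 1L, "id")
  structure(list(
    time = state$time,
    area = best$area,
    boundary_cells = ids[best$cells],
    n_cholangiocytes_lining = sum(types[best$cells] == "cholangiocyte"),
    polygon = best$poly
  ), class = "lumen_record")
}

#' @export
print.lumen_record <- function(x, ...) {
  cat(sprintf("<lumen: t = %.2f h, area = %.1f um^2, %d lining cells (%d cholangiocytes)>\n",
              x$time, x$area, length(x$boundary_cells),
              x$n_cholangiocytes_lining))
  invisible(x)
}

# Walk the free boundary; returns a list of candidate cavities
trace_cavities <- function(state, cls, min_area = 1) {
  cells <- state$cells
  C <- length(cells)
  if (!C) return(list())
  off <- cls$off
  N <- off[C + 1]
  pos <- do.call(rbind, lapply(cells, `[[`, "xy"))
  cellof <- cls$cellof
  free <- cls$elem_contact == 0L
  partner <- cls$elem_partner
  region <- unlist(lapply(cells, `[[`, "region"), use.names = FALSE)
  # ring-next for global element/node indexing
  nxt <- integer(N)
  for (c in seq_len(C)) {
    a <- off[c] + 1L; b <- off[c + 1]
    nxt[a:b] <- c((a + 1L):b, a)[seq_len(b - a + 1L)]
  }
  seeds <- which(free & region == 1L)
  visited <- logical(N)
  centroids <- do.call(rbind, lapply(cells, function(cl) polygon_centroid(cl$xy)))
  out <- list()
  for (s in seeds) {
    if (visited[s]) next
    cur <- s
    mode_walk <- TRUE
    trail <- integer(0)   # free elements of this trace (committed on success)
    pts <- matrix(0, 0, 2)
    seen <- integer(0)
    skiprun <- 0L
    ok <- TRUE
    for (stp in seq_len(3L * N + 10L)) {
      if (free[cur]) {
        if (visited[cur]) { ok <- FALSE; break }
        k <- match(cur, trail)
        if (!is.na(k)) {
          # closed a boundary cycle; drop the lead-in prefix
          pts <- pts[k:nrow(pts), , drop = FALSE]
          seen <- seen[k:length(seen)]
          break
        }
        trail <- c(trail, cur)
        pts <- rbind(pts, pos[cur, ])
        seen <- c(seen, cellof[cur])
        cur <- nxt[cur]
        mode_walk <- TRUE
        skiprun <- 0L
      } else if (mode_walk) {
        p <- partner[cur]
        if (is.na(p) || p < 0) { ok <- FALSE; break }  # CBM-bounded: not a lumen
        cur <- p + 1L
        mode_walk <- FALSE
        skiprun <- 0L
      } else {
        cur <- nxt[cur]
        skiprun <- skiprun + 1L
        # walked through more than a whole ring of contacts: lost
        if (skiprun > off[cellof[cur] + 1] - off[cellof[cur]]) {
          ok <- FALSE
          break
        }
      }
      if (stp == 3L * N + 10L) ok <- FALSE
    }
    visited[s] <- TRUE
    if (!ok || nrow(pts) < 3) next
    # cavity boundaries run clockwise (cell interiors on the outside)
    As <- polygon_area(pts)
    if (As >= 0) next
    A <- -As
    if (A < min_area) next
    # a cavity contains no cells: reject hull-like traces
    inside <- cpp_points_in_ring(centroids, pts)
    if (any(inside)) next
    if (nrow(state$cbm)) {
      bc <- cbind(state$cbm$x, state$cbm$y)
      if (any(cpp_points_in_ring(bc, pts))) next
    }
    visited[trail] <- TRUE
    out[[length(out) + 1]] <- list(area = A, poly = pts,
                                   cells = sort(unique(seen)))
  }
  out
}

#' Apical and basal arc lengths of a polarized cell
#'
#' Sums the current element lengths over the apical and basal surface
#' regions; the ratio basal/apical quantifies apical constriction (> 1 for
#' wedge-shaped, apically constricted cells).
#'
#' @param cell A polarized cell. The stored (material) region labels are
#'   used when present - the anatomical poles are persistent membrane
#'   domains - and are derived from the polarity cones otherwise.
#' @return List with `apical`, `basal` (um) and `ratio` = basal/apical;
#'   `NA` (flagged) for unpolarized cells.
#' @export
measure_apical_basal <- function(cell) {
  if (is.null(cell$polarity)) {
    return(list(apical = NA_real_, basal = NA_real_, ratio = NA_real_,
                polarized = FALSE))
  }
  if (all(cell$region == 0L)) cell <- classify_regions(cell)
  L <- edge_lengths(cell$xy)
  ap <- sum(L[cell$region == region_codes[["apical"]]])
  ba <- sum(L[cell$region == region_codes[["basal"]]])
  list(apical = ap, basal = ba,
       ratio = if (ap > 0) ba / ap else NA_real_, polarized = TRUE)
}

#' Ensemble statistics over stochastic realizations
#'
#' Pointwise mean, +-2 SD band (clipped at zero for non-negative
#' quantities such as areas) and min/max over a set of per-seed time
#' series on a common grid. Mismatched grids are resampled onto the first
#' run's grid with a warning.
#'
#' @param runs List of data frames with columns `time` and `value` (or
#'   `area`).
#' @param clip_zero Clip the lower band at 0?
#' @return Data frame: time, mean, sd, lo, hi, min, max.
#' @export
ensemble_stats <- function(runs, clip_zero = TRUE) {
  if (length(runs) < 2) stop("need at least two runs")
  getv <- function(r) if ("value" %in% names(r)) r$value else r$area
  tg <- runs[[1]]$time
  vals <- lapply(runs, function(r) {
    if (length(r$time) != length(tg) || any(abs(r$time - tg) > 1e-9)) {
      warning("mismatched time grids; resampling")
      approx(r$time, getv(r), xout = tg, rule = 2)$y
    } else getv(r)
  })
  m <- do.call(cbind, vals)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  lo <- mu - 2 * s
  if (clip_zero) lo <- pmax(0, lo)
  data.frame(time = tg, mean = mu, sd = s, lo = lo, hi = mu + 2 * s,
             min = apply(m, 1, min), max = apply(m, 1, max))
}
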