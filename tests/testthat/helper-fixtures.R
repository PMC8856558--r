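# Shared fixtures, built in code at test time.

# reduced-resolution configuration used throughout the suite
fast_cfg <- function() {
  cfg <- default_config()
  cfg$dcm$n_nodes <- 36
  cfg
}

# a relaxed adhering pair of deformable cells
relaxed_pair <- function(cfg = fast_cfg(), radius = 10, gap = -1,
                         relax_s = 1200) {
  a <- build_cell(c(-radius - gap / 2, 0), radius, 36, "hepatoblast", cfg,
                  id = 1L)
  b <- build_cell(c(radius + gap / 2, 0), radius, 36, "hepatoblast", cfg,
                  id = 2L)
  a$D <- 0; b$D <- 0
  st <- mech_state(list(a, b), cfg = cfg)
  if (relax_s > 0) st <- advance_mechanics(st, relax_s)
  st
}

# two parallel flat plates (rigid rings) facing each other across `gap`;
# plate length L along x, thickness th, element length ~el
flat_plate_pair <- function(L = 24, th = 4, gap = 0.05, el = 0.5,
                            cfg = fast_cfg()) {
  mk <- function(y0, id) {
    xs <- seq(-L / 2, L / 2, by = el)
    top <- cbind(rev(xs), y0 + th)
    bot <- cbind(xs, y0)
    sideR <- cbind(L / 2, y0 + seq(el, th - el, by = el))
    sideL <- cbind(-L / 2, y0 + rev(seq(el, th - el, by = el)))
    xy <- rbind(bot, sideR, top, sideL)  # CCW
    cl <- lumensim:::new_cell_from_ring(xy, "hepatoblast", cfg, id = id)
    cl$fixed <- TRUE
    cl$D <- 0
    cl
  }
  upper <- mk(gap / 2, 1L)        # lower surface of upper plate at +gap/2
  lower <- mk(-th - gap / 2, 2L)  # upper surface of lower plate at -gap/2
  mech_state(list(upper, lower), cfg = cfg)
}

# annulus of arc-block cells around a circular cavity of radius r_in
annulus_fixture <- function(r_in = 10, r_out = 18, nblocks = 6,
                            cfg = fast_cfg()) {
  cells <- list()
  for (b in seq_len(nblocks)) {
    a0 <- (b - 1) * 2 * pi / nblocks - 0.02  # slight overlap => contact
    a1 <- b * 2 * pi / nblocks + 0.02
    tin <- seq(a1, a0, length.out = 30)
    tout <- seq(a0, a1, length.out = 30)
    xy <- rbind(cbind(r_out * cos(tout), r_out * sin(tout)),
                cbind(r_in * cos(tin), r_in * sin(tin)))
    cl <- lumensim:::new_cell_from_ring(xy, "cholangiocyte", cfg, id = b)
    # inner-arc elements face the cavity: label them apical
    n <- nrow(xy)
    cl$region <- integer(n)
    cl$region[31:(n - 1)] <- 1L
    cl$fixed <- TRUE
    cells[[b]] <- cl
  }
  mech_state(cells, cfg = cfg)
}

# pixel-rasterization oracle for a measured cavity polygon: pixels inside
# the traced polygon and not inside any cell, at resolution h
raster_cavity_area <- function(state, poly, h = 0.1) {
  xr <- range(poly[, 1]) + c(-1, 1)
  yr <- range(poly[, 2]) + c(-1, 1)
  gx <- seq(xr[1], xr[2], by = h)
  gy <- seq(yr[1], yr[2], by = h)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inpoly <- lumensim:::cpp_points_in_ring(pts, poly)
  incell <- rep(FALSE, nrow(pts))
  for (cl in state$cells) {
    box <- inpoly & !incell &
      pts[, 1] >= min(cl$xy[, 1]) & pts[, 1] <= max(cl$xy[, 1]) &
      pts[, 2] >= min(cl$xy[, 2]) & pts[, 2] <= max(cl$xy[, 2])
    if (any(box)) {
      incell[box] <- incell[box] |
        lumensim:::cpp_points_in_ring(pts[box, , drop = FALSE], cl$xy)
    }
  }
  sum(inpoly & !incell) * h^2
}

# central finite-difference gradient of an energy term wrt all node
# coordinates of a state
fd_gradient <- function(state, term, h = 1e-6) {
  g <- lapply(state$cells, function(cl) matrix(0, nrow(cl$xy), 2))
  for (ci in seq_along(state$cells)) {
    for (i in seq_len(nrow(state$cells[[ci]]$xy))) {
      for (k in 1:2) {
        sp <- state; sm <- state
        sp$cells[[ci]]$xy[i, k] <- sp$cells[[ci]]$xy[i, k] + h
        sm$cells[[ci]]$xy[i, k] <- sm$cells[[ci]]$xy[i, k] - h
        g[[ci]][i, k] <- -(dcm_energy(sp, term) - dcm_energy(sm, term)) /
          (2 * h)
      }
    }
  }
  do.call(rbind, g)
}
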