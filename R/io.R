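# Serialization: lossless JSON snapshots (restartable, including RNG
# state), legacy-VTK polygon meshes for visualization, CSV time series and
# event logs, and a run manifest per output directory.

#' Write a lossless snapshot of a state
#'
#' Serializes every field needed to resume the simulation - node
#' positions, rest lengths, labels, marks, particles, CBM cells, clocks
#' and the RNG state (both the R stream and the mechanics stream counter)
#' - to JSON at full floating-point precision.
#'
#' @param state A [mech_state()].
#' @param path Output file (.json).
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, path) {
  ser_cell <- function(cl) {
    p <- cl$polarity
    list(id = cl$id, type = cl$type, xy = cl$xy, rest = cl$rest,
         rest0 = cl$rest0,
         base_rest = cl$base_rest, kel = cl$kel, kb = cl$kb, th0 = cl$th0,
         Aref = cl$Aref, birthA = cl$birthA, KV = cl$KV, Wmul = cl$Wmul,
         D = cl$D, fixed = cl$fixed,
         polarity = if (is.null(p)) NULL else
           list(abp = p$abp, pcp = p$pcp, alpha = p$alpha,
                gamma_tj = p$gamma_tj),
         region = cl$region, marked = cl$marked, quiescent = cl$quiescent,
         tau = cl$tau, age = cl$age, sig_timer = cl$sig_timer,
         secreting = cl$secreting, constricting = cl$constricting,
         cfac = cl$cfac, kel0 = cl$kel0,
         ac_set = cl$ac_set, ac_abp = cl$ac_abp,
         fext = cl$fext)
  }
  obj <- list(
    format = "lumensim-snapshot-1",
    time = state$time, seed = state$seed, counter = state$counter,
    next_id = state$next_id, next_tp = state$next_tp, P_L = state$P_L,
    founder_id = state$founder_id,
    rng_state = if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL,
    config = state$config,
    cells = lapply(state$cells, ser_cell),
    cbm = as.list(state$cbm),
    particles = as.list(state$particles)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a snapshot back into a state
#'
#' Inverse of [write_snapshot()]; restores the R RNG state so that a
#' resumed run continues the original random sequence.
#'
#' @param path Snapshot file.
#' @param restore_rng Restore the saved R RNG state?
#' @return A [mech_state()].
#' @export
read_snapshot <- function(path, restore_rng = TRUE) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "lumensim-snapshot-1")) {
    stop("parse error: not a lumensim snapshot: ", path)
  }
  as_cell <- function(sc) {
    cl <- sc
    cl$xy <- if (is.matrix(sc$xy)) sc$xy else
      matrix(unlist(sc$xy), ncol = 2, byrow = TRUE)
    cl$id <- as.integer(sc$id)
    cl$region <- as.integer(sc$region)
    cl$marked <- as.integer(sc$marked)
    cl$sig_timer <- if (is.null(sc$sig_timer)) NA_real_ else sc$sig_timer
    if (!is.null(sc$polarity)) {
      cl$polarity <- polarity_state(unlist(sc$polarity$abp),
                                    unlist(sc$polarity$pcp),
                                    sc$polarity$alpha, sc$polarity$gamma_tj)
    } else cl$polarity <- NULL
    cl$fext <- unlist(sc$fext)
    cl$cfac <- as.numeric(unlist(sc$cfac))
    cl$kel0 <- as.numeric(unlist(sc$kel0))
    if (!is.null(sc$ac_set)) {
      cl$ac_set <- list(apical = as.integer(unlist(sc$ac_set$apical)),
                        tj = as.integer(unlist(sc$ac_set$tj)))
      cl$ac_abp <- as.numeric(unlist(sc$ac_abp))
    }
    class(cl) <- "dcm_cell"
    cl
  }
  cells <- lapply(obj$cells, as_cell)
  cfg <- obj$config
  cfg$polarity$constriction <- unlist(cfg$polarity$constriction)
  cfg$fate$cycling_targets <- unlist(cfg$fate$cycling_targets)
  st <- mech_state(cfg = cfg, seed = obj$seed)
  st$cells <- cells
  if (length(obj$cbm$id)) st$cbm <- as.data.frame(obj$cbm)
  if (length(obj$particles$id)) st$particles <- as.data.frame(obj$particles)
  st$time <- obj$time
  st$counter <- obj$counter
  st$next_id <- as.integer(obj$next_id)
  st$next_tp <- as.integer(obj$next_tp)
  st$P_L <- obj$P_L
  st$founder_id <- obj$founder_id
  if (restore_rng && !is.null(obj$rng_state)) {
    assign(".Random.seed", as.integer(obj$rng_state), envir = globalenv())
  }
  st
}

#' Export a state as a legacy-VTK polygon mesh
#'
#' Writes an ASCII legacy VTK POLYDATA file: one polygon per deformable
#' cell, one vertex per center-based cell, with `cell_type` and `radius`
#' as cell data and `region`/`marked` as point data (-1 on CBM points).
#' Tracer particles are appended as additional vertices (`cell_type` -1).
#'
#' @param state A [mech_state()].
#' @param path Output file (.vtk).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(state, path) {
  type_code <- c(hepatoblast = 0L, cholangiocyte = 1L, mesenchyme = 2L,
                 endothelium = 3L, envelope = 4L)
  cells <- state$cells
  npc <- vapply(cells, function(cl) nrow(cl$xy), 1L)
  pts <- do.call(rbind, c(lapply(cells, `[[`, "xy"),
                          list(cbind(state$cbm$x, state$cbm$y),
                               cbind(state$particles$x, state$particles$y))))
  if (is.null(pts)) pts <- matrix(0, 0, 2)
  C <- length(cells); M <- nrow(state$cbm); K <- nrow(state$particles)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("lumensim t=%.6f h", state$time)
  w("ASCII")
  w("DATASET POLYDATA")
  w("POINTS %d float", nrow(pts))
  writeLines(sprintf("%.6f %.6f 0", pts[, 1], pts[, 2]), con)
  if (C) {
    w("POLYGONS %d %d", C, C + sum(npc))
    off <- c(0L, cumsum(npc))
    for (c in seq_len(C)) {
      w("%d %s", npc[c], paste(off[c]:(off[c + 1] - 1L), collapse = " "))
    }
  }
  if (M + K > 0) {
    w("VERTICES %d %d", M + K, 2 * (M + K))
    base <- sum(npc)
    writeLines(sprintf("1 %d", base + seq_len(M + K) - 1L), con)
  }
  w("CELL_DATA %d", C + M + K)
  w("SCALARS cell_type int 1")
  w("LOOKUP_TABLE default")
  tc <- c(vapply(cells, function(cl) type_code[[cl$type]], 1L),
          if (M) type_code[state$cbm$type] else integer(),
          rep(-1L, K))
  writeLines(sprintf("%d", tc), con)
  w("SCALARS radius float 1")
  w("LOOKUP_TABLE default")
  rad <- c(vapply(cells, cell_radius_eff, 1), state$cbm$R, rep(0.2, K))
  writeLines(sprintf("%.4f", rad), con)
  w("POINT_DATA %d", nrow(pts))
  w("SCALARS region int 1")
  w("LOOKUP_TABLE default")
  reg <- c(unlist(lapply(cells, `[[`, "region")), rep(-1L, M + K))
  writeLines(sprintf("%d", reg), con)
  w("SCALARS marked int 1")
  w("LOOKUP_TABLE default")
  mk <- c(unlist(lapply(cells, `[[`, "marked")), rep(-1L, M + K))
  writeLines(sprintf("%d", mk), con)
  invisible(path)
}

#' Write the measured time series of a run to CSV
#'
#' @param series Data frame (`state$series` of [run_model()]), or a list
#'   of them (one per seed, written with a `seed` column).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  if (is.data.frame(series)) {
    write.csv(series, path, row.names = FALSE)
  } else {
    for (k in seq_along(series)) series[[k]]$seed <- k
    write.csv(do.call(rbind, series), path, row.names = FALSE)
  }
  invisible(path)
}

#' Write the event log (divisions, differentiations, quiescence) to CSV
#' @param state A [mech_state()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_events <- function(state, path) {
  write.csv(state$events, path, row.names = FALSE)
  invisible(path)
}

# rolling polynomial hash over a string (manifest config fingerprint)
fnv1a <- function(s) {
  b <- utf8ToInt(s)
  h <- 17
  for (x in b) h <- (h * 31 + x) %% 268435399
  sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Records the configuration hash, seed list, package version, start/end
#' times and output paths of a run in `manifest.json` inside `dir`.
#'
#' @param dir Output directory.
#' @param cfg Configuration used.
#' @param seeds Integer seed vector.
#' @param outputs Character vector of files written.
#' @param started,finished POSIXct timestamps.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(dir, cfg, seeds, outputs = character(),
                           started = Sys.time(), finished = Sys.time()) {
  path <- file.path(dir, "manifest.json")
  obj <- list(
    config_hash = fnv1a(yaml::as.yaml(cfg, precision = 15)),
    seeds = as.integer(seeds),
    code_version = as.character(utils::packageVersion("lumensim")),
    started = format(started, "%Y-%m-%dT%H:%M:%S"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S"),
    outputs = outputs
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
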