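# Serialization: time-series CSV, legacy-VTK snapshots, YAML configuration
# and the JSON run manifest.

fmt_num <- function(x) {
  # shortest decimal representation that round-trips the double exactly
  vapply(x, function(v) {
    for (d in 1:16) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

#' Write the recorded time series to CSV
#'
#' One row per recorded day with header
#' `day,A_avg,MR_avg,MA_avg,F_avg,MAL,T,B,P,FL`.  Values are written with
#' 17 significant digits, so reading the file back reproduces the
#' in-memory doubles exactly and two identical runs produce byte-identical
#' files.
#'
#' @param result an `imm_sim` from [run_simulation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  stopifnot(inherits(result, "imm_sim"))
  s <- result$series
  if (nrow(s) == 0) abort("empty result")
  lines <- c(
    paste(names(s), collapse = ","),
    vapply(seq_len(nrow(s)), function(r) {
      paste(c(as.character(s$day[r]),
              vapply(s[r, -1], fmt_num, character(1))), collapse = ",")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a time-series CSV written by [write_timeseries()]
#'
#' @param path file path.
#' @return a tibble with the same columns as `imm_sim$series`.
#' @export
read_timeseries <- function(path) {
  d <- utils::read.csv(path, colClasses = c(day = "integer"))
  as_tibble(d)
}

#' Write a tissue snapshot as a legacy-VTK structured-points file
#'
#' ASCII legacy VTK with four point-data scalar arrays (`A`, `MR`, `MA`,
#' `F`), `DIMENSIONS nx ny nz`, `SPACING dx dy dz`, origin at (0, 0, 0).
#' Point values follow the VTK structured-points convention: x varies
#' fastest, then y, then z (the native layout of R's 3D arrays).
#'
#' @param tissue an `imm_tissue` state (e.g. an element of
#'   `imm_sim$snapshots`).
#' @param grid the [grid_spec()] the fields live on.
#' @param day the simulated day, recorded in the file header.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(tissue, grid, day, path) {
  stopifnot(inherits(grid, "imm_grid"))
  dims <- grid_dims(grid)
  for (f in c("A", "M_R", "M_A", "F")) {
    if (!identical(dim(tissue[[f]]), as.integer(dims))) {
      abort(paste0("field ", f, " does not match the grid"))
    }
  }
  n <- prod(dims)
  header <- c(
    "# vtk DataFile Version 3.0",
    sprintf("immunecouple tissue fields, day %s", format(day)),
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
    sprintf("SPACING %s %s %s", fmt_num(grid$dx), fmt_num(grid$dy),
            fmt_num(grid$dz)),
    "ORIGIN 0 0 0",
    sprintf("POINT_DATA %d", n)
  )
  arr_block <- function(name, a) {
    c(sprintf("SCALARS %s double 1", name),
      "LOOKUP_TABLE default",
      vapply(as.vector(a), fmt_num, character(1)))
  }
  writeLines(c(header,
               arr_block("A", tissue$A),
               arr_block("MR", tissue$M_R),
               arr_block("MA", tissue$M_A),
               arr_block("F", tissue$F)),
             path)
  invisible(path)
}

#' Read a legacy-VTK snapshot written by [write_snapshot()]
#'
#' @param path file path.
#' @return a list with `dims`, `spacing` and the four field arrays `A`,
#'   `M_R`, `M_A`, `F`.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(grep("^DIMENSIONS", lines, value = TRUE),
                              " ")[[1]][-1])
  spacing <- as.numeric(strsplit(grep("^SPACING", lines, value = TRUE),
                                 " ")[[1]][-1])
  n <- prod(dims)
  starts <- grep("^SCALARS", lines)
  fields <- list()
  for (s in starts) {
    name <- strsplit(lines[s], " ")[[1]][2]
    vals <- as.numeric(lines[(s + 2):(s + 1 + n)])
    fields[[name]] <- array(vals, dim = dims)
  }
  list(dims = dims, spacing = spacing,
       A = fields$A, M_R = fields$MR, M_A = fields$MA, F = fields$F)
}

#' Write every stored snapshot of a run
#'
#' @param result an `imm_sim` whose config requested `snapshot_days`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return the written paths, invisibly.
#' @export
write_snapshots <- function(result, dir, prefix = "snapshot") {
  stopifnot(inherits(result, "imm_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (day in names(result$snapshots)) {
    p <- file.path(dir, sprintf("%s_day%03d.vtk", prefix, as.integer(day)))
    write_snapshot(result$snapshots[[day]], result$config$grid,
                   as.integer(day), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

config_to_list <- function(config) {
  lay <- config$layout
  list(
    scenario = config$scenario,
    num_days = config$num_days,
    dt = config$dt,
    iter_per_day = config$iter_per_day,
    tol = config$tol,
    stop_on_tol = config$stop_on_tol,
    record_stride = config$record_stride,
    snapshot_days = config$snapshot_days,
    grid = config$grid[c("nx", "ny", "nz", "dx", "dy", "dz", "voxel_volume")],
    vessels = list(
      blood_x = if (!is.null(lay$blood_xz)) as.integer(lay$blood_xz[, 1]),
      blood_z = if (!is.null(lay$blood_xz)) as.integer(lay$blood_xz[, 2]),
      lymph_x = if (!is.null(lay$lymph_xz)) as.integer(lay$lymph_xz[, 1]),
      lymph_z = if (!is.null(lay$lymph_xz)) as.integer(lay$lymph_xz[, 2])
    ),
    parameters = unclass(config$params)
  )
}

#' Write / read a simulation configuration as structured text (YAML)
#'
#' The file mirrors [simulation_config()]: top-level stepping keys, a
#' `grid` section, a `vessels` section (explicit column positions, omitted
#' for the default layout) and a `parameters` section.  Any key omitted
#' from the file takes the published default, so a minimal file may
#' contain just `scenario: case3`.  Numbers are written with 17
#' significant digits so a write/read round trip is exact.
#'
#' @param config an `imm_config`.
#' @param path file path.
#' @return `write_config()`: `path` invisibly; `read_config()`: an
#'   `imm_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "imm_config"))
  l <- config_to_list(config)
  l$vessels <- Filter(Negate(is.null), l$vessels)
  if (length(l$vessels) == 0) l$vessels <- NULL
  writeLines(yaml::as.yaml(l, precision = 17), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  l <- yaml::read_yaml(path)
  grid <- do.call(grid_spec, l$grid %||% list())
  layout <- NULL
  if (!is.null(l$vessels) && length(l$vessels)) {
    v <- l$vessels
    layout <- vessel_layout(
      blood_xz = if (!is.null(v$blood_x)) cbind(v$blood_x, v$blood_z),
      lymph_xz = if (!is.null(v$lymph_x)) cbind(v$lymph_x, v$lymph_z)
    )
  }
  params <- default_parameters()
  if (!is.null(l$parameters)) {
    params <- do.call(modify_parameters, c(list(params), l$parameters))
  }
  args <- l[intersect(names(l), c("scenario", "num_days", "dt",
                                  "iter_per_day", "tol", "stop_on_tol",
                                  "record_stride", "snapshot_days"))]
  do.call(simulation_config,
          c(args, list(grid = grid, layout = layout, params = params)))
}

#' Run manifest: everything needed to reproduce a run
#'
#' JSON record of the fully resolved configuration (all defaults
#' materialized), the package version, wall time, stopping reason and the
#' negative-clamp count.  The model is deterministic, so re-running from a
#' manifest reproduces the result exactly.
#'
#' @param result an `imm_sim`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path) {
  stopifnot(inherits(result, "imm_sim"))
  m <- list(
    package = "immunecouple",
    version = as.character(utils::packageVersion("immunecouple")),
    config = config_to_list(result$config),
    stopping_reason = result$stopping_reason,
    elimination_day = result$elimination_day,
    negative_clamp_count = result$negative_clamp_count,
    wall_time_s = result$wall_time
  )
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Re-create the configuration stored in a manifest
#'
#' @param path a manifest written by [write_manifest()].
#' @return an `imm_config`.
#' @export
config_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  l <- m$config
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(l, precision = 17), tmp)
  read_config(tmp)
}
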