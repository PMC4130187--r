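# Simulation configuration, scenario presets, and the co-simulation driver.

.scenarios <- c("case1", "case2", "case3")

scenario_overrides <- function(scenario) {
  # case1: antigen alone -- no tissue immune cells, no vessel traffic.
  # case2: innate response only -- lymph-node coupling rates zeroed.
  # case3: full coupled model.
  switch(scenario,
    case1 = list(MR0 = 0, alpha_MR = 0, alpha_MA = 0, alpha_F = 0),
    case2 = list(alpha_MA = 0, alpha_F = 0),
    case3 = list()
  )
}

scenario_days <- function(scenario) {
  switch(scenario, case1 = 100L, case2 = 100L, case3 = 30L)
}

#' Simulation configuration
#'
#' Collects everything one run needs: scenario wiring, grid, vessel
#' layout, parameters, time stepping and output options.  The constructor
#' enforces `dt * iter_per_day == 1` (the day loop advances exactly one
#' day) and the explicit-Euler diffusion stability bound
#' `max(D) * dt * (1/dx^2 + 1/dy^2 + 1/dz^2) < 1/2`.
#'
#' Scenario wiring is applied to the parameter set before user overrides:
#' `"case1"` zeroes `MR0`, `alpha_MR`, `alpha_MA` and `alpha_F` so only
#' the antigen equation is active; `"case2"` zeroes the two lymph-node
#' coupling rates (`alpha_MA`, `alpha_F`), leaving the innate tissue
#' response; `"case3"` is the full coupled model.
#'
#' @param scenario `"case1"`, `"case2"` or `"case3"`.
#' @param grid an [grid_spec()].
#' @param layout an [vessel_layout()] or `NULL` for the default.
#' @param params base parameter set before scenario wiring.
#' @param num_days simulation horizon in days (defaults: 100 for cases 1-2,
#'   30 for case 3).
#' @param dt Euler time step in days.
#' @param iter_per_day steps per simulated day; must equal `1/dt`.
#' @param tol stopping threshold on the total amount of tissue antigen
#'   (`sum(A) * voxel_volume`).
#' @param stop_on_tol stop early once the total antigen falls to `tol`?
#' @param record_stride days between recorded samples.
#' @param snapshot_days integer days at which full tissue fields are kept.
#' @param ... named parameter overrides applied after scenario wiring,
#'   e.g. `rho_F = 1.02e5`.
#' @return an object of class `imm_config`.
#' @examples
#' cfg <- simulation_config("case3")
#' cfg$num_days
#' @export
simulation_config <- function(scenario = c("case3", "case1", "case2"),
                              grid = grid_spec(),
                              layout = NULL,
                              params = default_parameters(),
                              num_days = NULL,
                              dt = 1e-4,
                              iter_per_day = round(1 / dt),
                              tol = 1e-6,
                              stop_on_tol = TRUE,
                              record_stride = 1L,
                              snapshot_days = integer(0),
                              ...) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(grid, "imm_grid"), inherits(params, "imm_params"))
  num_days <- as.integer(num_days %||% scenario_days(scenario))
  if (num_days < 1) abort("num_days must be >= 1")
  if (!isTRUE(all.equal(dt * iter_per_day, 1))) {
    abort("dt * iter_per_day must equal 1 day")
  }
  params <- do.call(modify_parameters, c(list(params), scenario_overrides(scenario)))
  params <- modify_parameters(params, ...)

  dmax <- max(params$D_A, params$D_MR, params$D_MA, params$D_F)
  cfl <- dmax * dt * (1 / grid$dx^2 + 1 / grid$dy^2 + 1 / grid$dz^2)
  if (cfl >= 0.5) {
    abort(sprintf(
      "explicit diffusion unstable: max(D)*dt*(1/dx^2+1/dy^2+1/dz^2) = %.3g >= 0.5", cfl))
  }

  if (is.null(layout)) layout <- vessel_layout()
  vessels <- build_vessel_map(grid, layout)
  if (scenario == "case3" &&
      (vessels$V_LV <= 0 || vessels$V_BV <= 0)) {
    abort("the coupled scenario needs at least one blood and one lymph vessel")
  }

  structure(
    list(scenario = scenario, grid = grid, layout = layout,
         params = params, num_days = num_days, dt = dt,
         iter_per_day = as.integer(iter_per_day), tol = tol,
         stop_on_tol = stop_on_tol,
         record_stride = as.integer(record_stride),
         snapshot_days = as.integer(snapshot_days)),
    class = "imm_config"
  )
}

#' Published scenario presets
#'
#' `scenario_preset("case1")` is the antigen-only run (no immune cells,
#' 100 days), `"case2"` the innate-only run (coupling rates zeroed,
#' 100 days) and `"case3"` the full coupled model (30 days).
#'
#' @param name scenario name.
#' @param ... passed on to [simulation_config()] (e.g. `num_days`,
#'   parameter overrides).
#' @return an `imm_config`.
#' @export
scenario_preset <- function(name, ...) {
  if (length(name) != 1 || !name %in% .scenarios) {
    abort(paste0("unknown scenario: ", paste(name, collapse = ", ")))
  }
  simulation_config(scenario = name, ...)
}

#' @export
print.imm_config <- function(x, ...) {
  cat(sprintf("<imm_config> scenario %s, %d days, dt = %g (%d steps/day), tol = %g\n",
              x$scenario, x$num_days, x$dt, x$iter_per_day, x$tol))
  print(x$grid)
  invisible(x)
}

.series_cols <- c("A_avg", "MR_avg", "MA_avg", "F_avg",
                  "MAL", "T", "B", "P", "FL")

#' Run the coupled simulation
#'
#' Advances the coupled tissue / lymph-node model with the explicit Euler
#' method, `iter_per_day` steps per day, recording the spatially averaged
#' tissue fields and the lymph-node scalars once per `record_stride` days
#' (day 0 included).  The run stops early once the total amount of tissue
#' antigen `sum(A) * voxel_volume` falls to `tol` (when `stop_on_tol`).
#'
#' @param config an [simulation_config()].
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation, for cross-checking on small problems).
#' @return an object of class `imm_sim` with elements
#'   `series` (tibble: `day`, `A_avg`, `MR_avg`, `MA_avg`, `F_avg`, `MAL`,
#'   `T`, `B`, `P`, `FL`), `total_antigen` (per recorded day),
#'   `elimination_day` (first day with total antigen at or below `tol`, or
#'   `NA`), `negative_clamp_count`, `stopping_reason`, `snapshots` (named
#'   list of tissue states), `config` and `wall_time` (seconds).
#' @examples
#' \donttest{
#' res <- run_simulation(scenario_preset("case3"))
#' glance(res)
#' }
#' @export
run_simulation <- function(config, engine = c("cpp", "r")) {
  stopifnot(inherits(config, "imm_config"))
  engine <- match.arg(engine)
  grid <- config$grid
  vessels <- build_vessel_map(grid, config$layout)
  st <- initial_state(grid, config$params, config$scenario)
  t0 <- proc.time()[["elapsed"]]

  if (engine == "cpp") {
    out <- run_engine(
      st$tissue$A, st$tissue$M_R, st$tissue$M_A, st$tissue$F,
      c(st$lymph$M_A_L, st$lymph$T, st$lymph$B, st$lymph$P, st$lymph$F_L),
      vessels$theta_BV, vessels$theta_LV,
      grid_dims(grid), c(grid$dx, grid$dy, grid$dz), grid$voxel_volume,
      config$params, config$dt, config$iter_per_day, config$num_days,
      config$tol, config$stop_on_tol, config$record_stride,
      config$snapshot_days)
    series <- as.data.frame(out$series)
    names(series) <- c(.series_cols, "total_A")
    day <- out$day
    elim <- if (out$elimination_day < 0) NA_integer_ else out$elimination_day
    clamp <- out$clamp_count
    stopped <- out$stopped_on_tol
    snapshots <- lapply(out$snapshots, function(s) {
      structure(s, class = "imm_tissue")
    })
  } else {
    r <- run_r_engine(st, config, grid, vessels)
    series <- r$series; day <- r$day; elim <- r$elim
    clamp <- r$clamp; stopped <- r$stopped; snapshots <- r$snapshots
  }

  structure(
    list(series = as_tibble(cbind(data.frame(day = as.integer(day)),
                                  series[.series_cols])),
         total_antigen = series$total_A,
         elimination_day = elim,
         negative_clamp_count = clamp,
         stopping_reason = if (stopped) "tolerance" else "horizon",
         snapshots = snapshots,
         config = config,
         wall_time = proc.time()[["elapsed"]] - t0),
    class = "imm_sim"
  )
}

# day-loop in plain R over euler_step(); used to cross-check the compiled
# engine on small grids / short horizons
run_r_engine <- function(st, config, grid, vessels) {
  tissue <- st$tissue; lymph <- st$lymph
  dV <- grid$voxel_volume
  clamp <- 0
  total <- function() sum(tissue$A) * dV
  rec_row <- function(day) {
    c(day = day,
      A_avg = mean(tissue$A), MR_avg = mean(tissue$M_R),
      MA_avg = mean(tissue$M_A), F_avg = mean(tissue$F),
      MAL = lymph$M_A_L, T = lymph$T, B = lymph$B, P = lymph$P,
      FL = lymph$F_L, total_A = total())
  }
  rows <- list(rec_row(0))
  snapshots <- list()
  if (0L %in% config$snapshot_days) snapshots[["0"]] <- tissue
  elim <- NA_integer_
  stopped <- FALSE
  for (day in seq_len(config$num_days)) {
    for (it in seq_len(config$iter_per_day)) {
      stp <- euler_step(tissue, lymph, config$params, grid, vessels, config$dt)
      tissue <- stp$tissue; lymph <- stp$lymph; clamp <- clamp + stp$clamped
    }
    if (is.na(elim) && total() <= config$tol) elim <- day
    due <- day %% max(config$record_stride, 1L) == 0L ||
      day == config$num_days ||
      (config$stop_on_tol && total() <= config$tol)
    if (due) rows[[length(rows) + 1L]] <- rec_row(day)
    if (day %in% config$snapshot_days) snapshots[[as.character(day)]] <- tissue
    if (config$stop_on_tol && total() <= config$tol) { stopped <- TRUE; break }
  }
  m <- as.data.frame(do.call(rbind, rows))
  list(series = m, day = m$day, elim = elim, clamp = clamp,
       stopped = stopped, snapshots = snapshots)
}

#' @export
print.imm_sim <- function(x, ...) {
  cat(sprintf("<imm_sim> scenario %s: %d recorded days, stopped on %s\n",
              x$config$scenario, nrow(x$series) - 1L, x$stopping_reason))
  if (!is.na(x$elimination_day)) {
    cat(sprintf("  antigen eliminated on day %d (total <= %g)\n",
                x$elimination_day, x$config$tol))
  } else {
    cat(sprintf("  antigen not eliminated; final total = %.4g\n",
                x$total_antigen[length(x$total_antigen)]))
  }
  cat(sprintf("  negative clamps: %g;  wall time: %.1f s\n",
              x$negative_clamp_count, x$wall_time))
  invisible(x)
}

#' Tidy a simulation result into a long tibble
#'
#' @param x an `imm_sim`.
#' @param ... unused.
#' @return a tibble with columns `day`, `compartment`, `value`, one row
#'   per recorded day and state variable.
#' @export
tidy.imm_sim <- function(x, ...) {
  tidyr::pivot_longer(x$series, -"day",
                      names_to = "compartment", values_to = "value")
}

#' One-row summary of a simulation result
#'
#' @param x an `imm_sim`.
#' @param ... unused.
#' @return a one-row tibble: scenario, days simulated, elimination day,
#'   peak day and value of the average antigen, final total antigen,
#'   negative-clamp count, stopping reason.
#' @export
glance.imm_sim <- function(x, ...) {
  s <- x$series
  tibble(
    scenario = x$config$scenario,
    days_simulated = max(s$day),
    elimination_day = as.integer(x$elimination_day),
    peak_antigen_day = s$day[which.max(s$A_avg)],
    peak_antigen = max(s$A_avg),
    final_total_antigen = x$total_antigen[length(x$total_antigen)],
    negative_clamp_count = x$negative_clamp_count,
    stopping_reason = x$stopping_reason
  )
}

#' Plot the recorded time series of a run
#'
#' @param object an `imm_sim`.
#' @param compartments which series to draw (default all nine).
#' @param log10 use a log10 y-axis (zeros dropped)?
#' @param ... unused.
#' @return a ggplot object, one facet per compartment.
#' @export
autoplot.imm_sim <- function(object, compartments = NULL, log10 = FALSE, ...) {
  d <- tidy(object)
  if (!is.null(compartments)) {
    d <- dplyr::filter(d, .data$compartment %in% compartments)
  }
  d$compartment <- factor(d$compartment, levels = .series_cols)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$day, .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~compartment, scales = "free_y") +
    ggplot2::labs(x = "day", y = "concentration (cells/mm^3)",
                  title = sprintf("Coupled immune simulation (%s)",
                                  object$config$scenario)) +
    ggplot2::theme_minimal()
  if (log10) p <- p + ggplot2::scale_y_log10()
  p
}
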