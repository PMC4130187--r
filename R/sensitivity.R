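# One-factor-at-a-time (OAT) sensitivity analysis of the coupled model.

# the 20 parameters assessed in the published sensitivity study
.oat_default_parameters <- c(
  "gamma_MA", "alpha_F", "MR0", "beta_A", "rho_F", "k_A",
  "b_p_p", "alpha_MA", "lambda_AF_MA", "b_p",
  "D_MR", "D_A", "lambda_MA", "b_p_b", "D_MA",
  "A0", "alpha_MR", "lambda_MR", "lambda_AF_MR", "b_T"
)

.oat_descriptions <- c(
  gamma_MA = "Macrophage activation rate",
  alpha_F = "Antibodies migration rate",
  MR0 = "Resting macrophage initial condition",
  beta_A = "Antigen replication rate",
  rho_F = "Antibodies release rate",
  k_A = "Antigen carrying capacity coefficient",
  b_p_p = "B cell expenditure to become plasma cell",
  alpha_MA = "Activated macrophage migration rate",
  lambda_AF_MA = "Activated macrophage phagocytosis rate of opsonized antigen",
  b_p = "T cell expenditure to stimulate B cell",
  D_MR = "Resting macrophage diffusion coefficient",
  D_A = "Antigen diffusion coefficient",
  lambda_MA = "Activated macrophage phagocytosis rate",
  b_p_b = "B cell stimuli coefficient",
  D_MA = "Activated macrophage diffusion coefficient",
  A0 = "Antigen initial condition",
  alpha_MR = "Resting macrophage source coefficient",
  lambda_MR = "Resting macrophage phagocytosis rate",
  lambda_AF_MR = "Resting macrophage phagocytosis rate of opsonized antigen",
  b_T = "T cell stimuli coefficient"
)

#' Normalised squared deviation between two time series
#'
#' The sensitivity score of one perturbed run against the reference run:
#' `sum((e_orig - e_k)^2) / sum(e_orig^2)` — a ratio of sums of squares
#' (no square root), so it is invariant under rescaling both series by a
#' common constant.  `norm = "l2"` gives the square-rooted variant for
#' comparison.
#'
#' @param e_orig reference series (must have a positive sum of squares).
#' @param e_k perturbed series of the same length.
#' @param norm `"sq"` (ratio of sums of squares, default) or `"l2"`.
#' @return a non-negative scalar; 0 iff the series are identical, 1 when
#'   `e_k` is identically zero or exactly doubles `e_orig`.
#' @examples
#' e <- c(1, 2, 3)
#' series_error(e, e)      # 0
#' series_error(e, 2 * e)  # 1
#' series_error(e, 0 * e)  # 1
#' @export
series_error <- function(e_orig, e_k, norm = c("sq", "l2")) {
  norm <- match.arg(norm)
  if (length(e_orig) != length(e_k)) {
    abort("series must have equal lengths")
  }
  denom <- sum(e_orig^2)
  if (denom <= 0) abort("reference series has zero norm")
  err <- sum((e_orig - e_k)^2) / denom
  if (norm == "l2") sqrt(err) else err
}

#' Specification of a one-at-a-time sensitivity analysis
#'
#' Each listed parameter is perturbed one at a time by each relative
#' variation in `variations` (e.g. `-0.5` halves it, `+1` doubles it),
#' the scenario is re-run, and the daily average-antigen series is scored
#' against the unperturbed run with [series_error()].  The `-1` (i.e.
#' -100%) variation is dropped automatically for `k_A`, which divides the
#' logistic term and cannot be zero; a message notes the exclusion.
#'
#' For initial-condition entries (`MR0`, `A0`) the perturbation scales the
#' initial value; for all others it scales the rate constant.
#'
#' @param parameters character vector of parameter names to assess
#'   (default: the 20 parameters of the published study).
#' @param variations relative perturbations (default
#'   `c(-1, -0.5, 0.5, 1, 2)`, i.e. -100% to +200%).
#' @param base_config the unperturbed run (default: the full coupled
#'   scenario, 30 days).  Early stopping is disabled internally so all
#'   runs yield series of equal length.
#' @param series_variable column of the recorded series entering the
#'   score (default `"A_avg"`, the spatial average of the antigen).
#' @param sample_stride keep every `sample_stride`-th recorded sample.
#' @return an object of class `imm_oat_spec`.
#' @export
sensitivity_spec <- function(parameters = .oat_default_parameters,
                             variations = c(-1, -0.5, 0.5, 1, 2),
                             base_config = scenario_preset("case3"),
                             series_variable = "A_avg",
                             sample_stride = 1L) {
  stopifnot(inherits(base_config, "imm_config"))
  bad <- setdiff(parameters, names(base_config$params))
  if (length(bad)) {
    abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
  }
  if (!series_variable %in% .series_cols) {
    abort(paste0("series_variable must be one of: ",
                 paste(.series_cols, collapse = ", ")))
  }
  if (any(variations < -1)) {
    abort("variations below -1 (-100%) would produce negative parameters")
  }
  grid <- expand.grid(parameter = parameters, variation = variations,
                      stringsAsFactors = FALSE)
  drop <- grid$parameter == "k_A" & grid$variation == -1
  if (any(drop)) {
    message("dropping the -100% variation for k_A (it divides the logistic term)")
    grid <- grid[!drop, ]
  }
  structure(
    list(parameters = parameters, variations = variations,
         cells = as_tibble(grid), base_config = base_config,
         series_variable = series_variable,
         sample_stride = as.integer(sample_stride)),
    class = "imm_oat_spec"
  )
}

oat_perturbed_config <- function(base_config, parameter, variation) {
  value <- base_config$params[[parameter]] * (1 + variation)
  cfg <- base_config
  cfg$params <- do.call(modify_parameters,
                        c(list(cfg$params), setNames(list(value), parameter)))
  cfg
}

#' Run the one-at-a-time sensitivity analysis
#'
#' Runs the base scenario once, then one run per (parameter, variation)
#' cell with only that parameter scaled by `1 + variation`; scores every
#' run against the base with [series_error()] on the chosen series; and
#' summarises each parameter by its maximum error over the variations
#' (`max_err`).  Runs that abort numerically are excluded from the
#' maximum with a warning.
#'
#' @param spec an [sensitivity_spec()].
#' @param engine passed to [run_simulation()].
#' @param verbose print one line per completed run?
#' @return an object of class `imm_oat` with `results` (tibble: parameter,
#'   variation, error), `summary` (tibble: parameter, description,
#'   max_err, argmax_variation, ranked by `max_err`), the base series and
#'   the spec.
#' @export
oat_analysis <- function(spec, engine = c("cpp", "r"), verbose = FALSE) {
  stopifnot(inherits(spec, "imm_oat_spec"))
  engine <- match.arg(engine)
  base_cfg <- spec$base_config
  base_cfg$stop_on_tol <- FALSE # equal-length series for every run
  base_cfg$snapshot_days <- integer(0)

  pick <- function(sim) {
    v <- sim$series[[spec$series_variable]]
    v[seq(1, length(v), by = spec$sample_stride)]
  }
  base <- run_simulation(base_cfg, engine = engine)
  e_orig <- pick(base)

  one <- function(parameter, variation) {
    cfg <- oat_perturbed_config(base_cfg, parameter, variation)
    err <- tryCatch(
      series_error(e_orig, pick(run_simulation(cfg, engine = engine))),
      error = function(e) {
        warn(sprintf("run failed for %s at %+.0f%%: %s",
                     parameter, 100 * variation, conditionMessage(e)))
        NA_real_
      })
    if (verbose) {
      message(sprintf("%-14s %+5.0f%%  error = %.4g",
                      parameter, 100 * variation, err))
    }
    err
  }
  results <- spec$cells
  results$error <- purrr::pmap_dbl(spec$cells, one)

  summary <- results |>
    dplyr::filter(!is.na(.data$error)) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      max_err = max(.data$error),
      argmax_variation = .data$variation[which.max(.data$error)],
      .groups = "drop") |>
    dplyr::mutate(description = dplyr::coalesce(
      unname(.oat_descriptions[.data$parameter]), .data$parameter)) |>
    dplyr::arrange(dplyr::desc(.data$max_err)) |>
    dplyr::select("parameter", "description", "max_err", "argmax_variation")

  structure(
    list(results = results, summary = summary, base_series = e_orig,
         spec = spec),
    class = "imm_oat"
  )
}

#' @export
print.imm_oat <- function(x, ...) {
  cat(sprintf("<imm_oat> %d parameters x %s variations (%d runs + base)\n",
              length(x$spec$parameters),
              paste(x$spec$variations, collapse = "/"),
              nrow(x$results)))
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' @export
tidy.imm_oat <- function(x, ...) x$summary

#' @export
glance.imm_oat <- function(x, ...) {
  tibble(
    n_parameters = length(x$spec$parameters),
    n_runs = nrow(x$results),
    n_failed = sum(is.na(x$results$error)),
    top_parameter = x$summary$parameter[1],
    top_max_err = x$summary$max_err[1]
  )
}

#' Plot the ranked sensitivity indices
#'
#' @param object an `imm_oat`.
#' @param ... unused.
#' @return a ggplot bar chart of `max_err` per parameter.
#' @export
autoplot.imm_oat <- function(object, ...) {
  d <- object$summary
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  ggplot2::ggplot(d, ggplot2::aes(.data$max_err, .data$parameter)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "maximum normalised squared deviation (max_err)",
                  y = NULL, title = "One-at-a-time sensitivity of the antigen series") +
    ggplot2::theme_minimal()
}
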