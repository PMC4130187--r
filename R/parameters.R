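# Model parameters: rate constants, carrying capacity, steady states and
# initial conditions for the coupled tissue / lymph-node immune model.

# canonical order; also the canonical set of names
.param_names <- c(
  # antigen (tissue)
  "beta_A", "k_A", "mu_A", "lambda_MR", "lambda_MA",
  "lambda_AF_MR", "lambda_AF_MA", "D_A",
  # resting macrophages (tissue)
  "mu_MR", "gamma_MA", "alpha_MR", "D_MR", "MR_star",
  # activated macrophages (tissue)
  "mu_MA", "alpha_MA", "D_MA",
  # antibodies (tissue)
  "D_F", "alpha_F",
  # lymph node
  "V_LN",
  "b_T", "rho_T", "b_p", "alpha_T", "T_star",
  "b_p_b", "rho_B", "alpha_B", "B_star",
  "b_p_p", "rho_P", "alpha_P", "P_star",
  "rho_F",
  # initial conditions
  "A0", "MR0", "MA0", "F0", "T0", "B0", "P0", "FL0"
)

#' Published default parameter set for the coupled immune model
#'
#' Returns the complete parameter set of the coupled tissue / lymph-node
#' model: reaction and transfer rates, diffusion coefficients, the antigen
#' carrying capacity, lymphocyte steady-state levels and all initial
#' conditions.  All rates are per day; concentrations are cells/mm^3.
#'
#' Some symbols appear under two names in the source literature on this
#' model family; this package uses one canonical name for each:
#' `gamma_MA` is the macrophage activation rate (sometimes written
#' gamma_AM), `lambda_AF_MR`/`lambda_AF_MA` are the phagocytosis rates of
#' opsonized antigen (sometimes lambda_FA|MR, lambda_FA|MA), and
#' `alpha_MA` is the activated-macrophage migration rate to the lymph node
#' (sometimes alpha_M).
#'
#' @param ... named overrides, e.g. `default_parameters(rho_F = 1.02e5)`.
#'   Unknown names are an error.
#'
#' @return An object of class `imm_params`: a named list with elements
#' \describe{
#'   \item{beta_A}{antigen replication rate, 2.0 /day}
#'   \item{k_A}{antigen carrying capacity, 50 cells/mm^3}
#'   \item{mu_A}{antigen natural decay, 0.1 /day}
#'   \item{lambda_MR, lambda_MA}{phagocytosis rates of antigen by resting /
#'     activated macrophages, 5.98e-3 and 5.98e-2 mm^3/(cell day)}
#'   \item{lambda_AF_MR, lambda_AF_MA}{destruction rates of opsonized
#'     (antibody-bound) antigen by resting / activated macrophages,
#'     1.66e-3 and 7.14e-2 mm^6/(cell^2 day)}
#'   \item{D_A, D_MR, D_MA, D_F}{diffusion coefficients of antigen and of
#'     resting macrophages, activated macrophages, antibodies}
#'   \item{mu_MR, mu_MA}{macrophage natural decay rates}
#'   \item{gamma_MA}{macrophage activation rate, 8.3e-2 mm^3/(cell day)}
#'   \item{alpha_MR}{resting-macrophage source rate at blood vessels, 4.0 /day}
#'   \item{MR_star}{resting-macrophage level sustained by the blood supply,
#'     4 cells/mm^3}
#'   \item{alpha_MA}{activated-macrophage migration rate through lymph
#'     vessels, 1e-3 /day}
#'   \item{alpha_F}{antibody migration rate through blood vessels, 0.43 /day}
#'   \item{V_LN}{lymph-node volume, 160 (model volume units)}
#'   \item{b_T, rho_T, b_p, alpha_T, T_star}{T-lymphocyte stimulation rate,
#'     progeny per division, expenditure rate on B-cell stimulation,
#'     homeostasis rate and steady state}
#'   \item{b_p_b, rho_B, alpha_B, B_star}{B-lymphocyte stimulation rate,
#'     progeny factor, homeostasis rate and steady state}
#'   \item{b_p_p, rho_P, alpha_P, P_star}{plasma-cell stimulation rate,
#'     progeny factor, homeostasis rate and steady state}
#'   \item{rho_F}{antibody release rate per plasma cell, 5.1e4 /day}
#'   \item{A0, MR0, MA0, F0, T0, B0, P0, FL0}{initial conditions (antigen in
#'     the injection block, resting macrophages everywhere, all others zero)}
#' }
#'
#' @examples
#' p <- default_parameters()
#' p$beta_A
#' default_parameters(rho_F = 2 * p$rho_F)$rho_F
#' @export
default_parameters <- function(...) {
  p <- list(
    beta_A = 2.0, k_A = 50.0, mu_A = 0.1,
    lambda_MR = 5.98e-3, lambda_MA = 5.98e-2,
    lambda_AF_MR = 1.66e-3, lambda_AF_MA = 7.14e-2,
    D_A = 3.7e-5,
    mu_MR = 0.033, gamma_MA = 8.3e-2, alpha_MR = 4.0,
    D_MR = 4.32e-2, MR_star = 4,
    mu_MA = 0.07, alpha_MA = 1e-3, D_MA = 0.3,
    D_F = 1.6e-2, alpha_F = 0.43,
    V_LN = 160,
    b_T = 1.7e-2, rho_T = 2.0, b_p = 1e5, alpha_T = 0.01, T_star = 8.4e-3,
    b_p_b = 6.02e3, rho_B = 16.0, alpha_B = 1.0, B_star = 8.4e-4,
    b_p_p = 2.3e6, rho_P = 3.0, alpha_P = 5.0, P_star = 8.4e-6,
    rho_F = 5.1e4,
    A0 = 2, MR0 = 4, MA0 = 0, F0 = 0, T0 = 0, B0 = 0, P0 = 0, FL0 = 0
  )
  p <- p[.param_names] # canonical order
  modify_parameters(structure(p, class = "imm_params"), ...)
}

#' Modify a parameter set
#'
#' @param params an `imm_params` object.
#' @param ... named replacements; names must be existing parameter names.
#' @return the modified `imm_params` object (validated).
#' @export
modify_parameters <- function(params, ...) {
  stopifnot(inherits(params, "imm_params"))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(params))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0("unknown parameter name(s): ",
                   paste(bad, collapse = ", ")))
    }
    params[names(dots)] <- dots
  }
  validate_parameters(params)
}

#' @rdname modify_parameters
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "imm_params"))
  miss <- setdiff(.param_names, names(params))
  if (length(miss)) {
    abort(paste0("missing parameter(s): ", paste(miss, collapse = ", ")))
  }
  vals <- unlist(params[.param_names])
  if (!all(is.finite(vals))) {
    abort("all parameters must be finite numbers")
  }
  if (any(vals < 0)) {
    abort(paste0("negative parameter(s): ",
                 paste(.param_names[vals < 0], collapse = ", ")))
  }
  if (params$k_A <= 0) abort("k_A must be > 0 (divides the logistic term)")
  if (params$V_LN <= 0) abort("V_LN must be > 0")
  params
}

#' @export
print.imm_params <- function(x, ...) {
  cat("<imm_params> coupled immune-model parameter set\n")
  df <- tibble(parameter = names(x), value = unlist(x))
  print(df, n = nrow(df))
  invisible(x)
}

#' @export
as.data.frame.imm_params <- function(x, ...) {
  data.frame(parameter = names(x), value = unlist(x), row.names = NULL)
}

#' @export
tidy.imm_params <- function(x, ...) {
  tibble(parameter = names(x), value = unlist(x))
}
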