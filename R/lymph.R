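# Lymph-node ODE right-hand sides and the tissue <-> node coupling
# integrals.

#' Vessel-averaged coupling quantities
#'
#' Discrete forms of the coupling integrals: the lymph-vessel-averaged
#' activated-macrophage concentration
#' `M_A_T = sum(theta_LV * M_A) * dV / V_LV` and the blood-vessel-averaged
#' antibody concentration `F_T = sum(theta_BV * F) * dV / V_BV`, where
#' `dV` is the voxel volume.  These feed the lymph-node ODEs as the
#' tissue-side concentrations seen by the vessels.
#'
#' @param tissue an `imm_tissue` state.
#' @param vessels an [build_vessel_map()] result with positive contact
#'   volumes.
#' @param grid an [grid_spec()].
#' @return a list with `M_A_T`, `F_T`, `V_LV`, `V_BV`.
#' @export
coupling_summary <- function(tissue, vessels, grid) {
  if (vessels$V_LV <= 0 || vessels$V_BV <= 0) {
    abort("coupling requires non-empty blood and lymph vessel maps")
  }
  dV <- grid$voxel_volume
  list(
    M_A_T = sum(vessels$theta_LV * tissue$M_A) * dV / vessels$V_LV,
    F_T = sum(vessels$theta_BV * tissue$F) * dV / vessels$V_BV,
    V_LV = vessels$V_LV,
    V_BV = vessels$V_BV
  )
}

#' Lymph-node right-hand side
#'
#' Time derivatives (per day) of the five well-mixed lymph-node variables:
#'
#' * `dM_A_L = alpha_MA * (M_A_T - M_A_L) * V_LV / V_LN` — signed exchange
#'   of antigen-presenting macrophages with the tissue, scaled by the
#'   vessel-contact to node volume ratio.
#' * `dT = b_T * (rho_T - 1) * T * M_A_L - b_p * M_A_L * T * B
#'   + alpha_T * (T_star - T)` — clonal expansion of helper T cells,
#'   expenditure on B-cell stimulation, homeostasis.
#' * `dB = b_p_b * (rho_B * T * M_A_L - T * M_A_L * B)
#'   + alpha_B * (B_star - B)`.
#' * `dP = b_p_p * rho_P * T * M_A_L * B + alpha_P * (P_star - P)`.
#' * `dF_L = rho_F * P - alpha_F * (F_L - F_T) * V_BV / V_LN` — antibody
#'   release by plasma cells minus the net export to the tissue.
#'
#' The two flux terms are the exact node-side counterparts of the
#' vessel-flux terms in the tissue equations: the tissue loses
#' `alpha * sum(theta * (X - X_L)) * dV` per day, which equals
#' `V_LN * dX_L` (flux part), so no cells or antibodies are created or
#' destroyed by the exchange.
#'
#' @param lymph an `imm_lymph` state.
#' @param coupling a [coupling_summary()].
#' @param params an [default_parameters()] set.
#' @return a named list `dM_A_L`, `dT`, `dB`, `dP`, `dF_L`.
#' @export
lymph_rhs <- function(lymph, coupling, params) {
  with(c(lymph, coupling, params), list(
    dM_A_L = alpha_MA * (M_A_T - M_A_L) * V_LV / V_LN,
    dT = b_T * (rho_T - 1) * T * M_A_L - b_p * M_A_L * T * B +
      alpha_T * (T_star - T),
    dB = b_p_b * (rho_B * T * M_A_L - T * M_A_L * B) +
      alpha_B * (B_star - B),
    dP = b_p_p * rho_P * T * M_A_L * B + alpha_P * (P_star - P),
    dF_L = rho_F * P - alpha_F * (F_L - F_T) * V_BV / V_LN
  ))
}
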