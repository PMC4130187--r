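# Single explicit-Euler step of the coupled system (reference R engine).

#' One explicit-Euler step of the coupled model
#'
#' Advances the tissue fields and lymph-node scalars by `dt` days with a
#' synchronous (Jacobi-style) forward-Euler update: every right-hand side
#' is evaluated at the pre-step state, so the result does not depend on
#' any update ordering.  Values driven below zero by the step are clamped
#' to zero and counted.
#'
#' This R implementation is the readable reference; [run_simulation()]
#' drives the identical arithmetic in compiled code.
#'
#' @param tissue,lymph the current state (see [initial_state()]).
#' @param params an [default_parameters()] set.
#' @param grid an [grid_spec()].
#' @param vessels an [build_vessel_map()] result.
#' @param dt time step in days.
#' @return a list with the updated `tissue`, `lymph` and the number of
#'   `clamped` values.
#' @export
euler_step <- function(tissue, lymph, params, grid, vessels, dt) {
  cp <- coupling_summary(tissue, vessels, grid)
  dT <- list(
    A = antigen_rhs(tissue, params, grid),
    M_R = resting_macrophage_rhs(tissue, params, grid, vessels),
    M_A = activated_macrophage_rhs(tissue, lymph, params, grid, vessels),
    F = antibody_rhs(tissue, lymph, params, grid, vessels)
  )
  dL <- lymph_rhs(lymph, cp, params)

  clamped <- 0L
  upd <- function(x, dx) {
    y <- x + dt * dx
    neg <- y < 0
    clamped <<- clamped + sum(neg)
    y[neg] <- 0
    y
  }
  tissue2 <- structure(
    list(A = upd(tissue$A, dT$A), M_R = upd(tissue$M_R, dT$M_R),
         M_A = upd(tissue$M_A, dT$M_A), F = upd(tissue$F, dT$F)),
    class = "imm_tissue"
  )
  lymph2 <- structure(
    list(M_A_L = upd(lymph$M_A_L, dL$dM_A_L), T = upd(lymph$T, dL$dT),
         B = upd(lymph$B, dL$dB), P = upd(lymph$P, dL$dP),
         F_L = upd(lymph$F_L, dL$dF_L)),
    class = "imm_lymph"
  )
  bad <- vapply(c(tissue2, lymph2), function(v) any(!is.finite(v)), logical(1))
  if (any(bad)) {
    abort(paste0("non-finite value in ", paste(names(bad)[bad], collapse = ", "),
                 " after Euler step"))
  }
  list(tissue = tissue2, lymph = lymph2, clamped = clamped)
}
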