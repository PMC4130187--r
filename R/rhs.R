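# Reaction-diffusion right-hand sides of the four tissue fields.
#
# These vectorized R versions define the model; the compiled engine used by
# run_simulation() implements the same arithmetic and is tested against
# them (and against scalar-loop oracles) on small grids.

shift_clamp <- function(f, axis, by) {
  # shift a 3D array by one voxel along `axis`, clamping at the boundary
  # (the clamped index realises the zero-normal-flux ghost value)
  d <- dim(f)
  idx <- lapply(d, seq_len)
  i <- idx[[axis]] + by
  i[i < 1] <- 1L
  i[i > d[axis]] <- d[axis]
  idx[[axis]] <- i
  do.call(`[`, c(list(f), idx, list(drop = FALSE)))
}

#' Discrete Laplacian with homogeneous Neumann boundaries
#'
#' Seven-point second-difference stencil
#' `(f[i+1] - 2 f[i] + f[i-1]) / dx^2` summed over the three axes.  The
#' zero-normal-flux boundary condition is imposed by mirroring: the ghost
#' value outside a boundary face equals the boundary voxel's own value, so
#' no mass crosses the face and `sum(laplacian(f)) == 0` exactly.
#'
#' @param field a 3D array matching `grid`.
#' @param grid an [grid_spec()].
#' @return a 3D array of the same shape.
#' @examples
#' g <- grid_spec(5, 5, 5)
#' all(laplacian(array(3, c(5, 5, 5)), g) == 0)
#' @export
laplacian <- function(field, grid) {
  stopifnot(inherits(grid, "imm_grid"))
  if (!identical(dim(field), as.integer(grid_dims(grid)))) {
    abort("field shape does not match the grid")
  }
  (shift_clamp(field, 1L, 1L) - 2 * field + shift_clamp(field, 1L, -1L)) / grid$dx^2 +
  (shift_clamp(field, 2L, 1L) - 2 * field + shift_clamp(field, 2L, -1L)) / grid$dy^2 +
  (shift_clamp(field, 3L, 1L) - 2 * field + shift_clamp(field, 3L, -1L)) / grid$dz^2
}

#' Tissue right-hand sides
#'
#' Pointwise time derivatives (per day) of the four tissue fields:
#'
#' * `antigen_rhs()`: logistic replication `beta_A * A * (1 - A / k_A)`,
#'   natural decay `mu_A * A`, phagocytosis by resting and activated
#'   macrophages (`lambda_MR`, `lambda_MA`), destruction of opsonized
#'   antigen (`lambda_AF_MR`, `lambda_AF_MA`, trilinear in A, F and the
#'   macrophage field) and diffusion.
#' * `resting_macrophage_rhs()`: natural decay, consumption by activation
#'   (`gamma_MA * M_R * A`), replenishment from the blood
#'   `alpha_MR * theta_BV * (MR_star - M_R)` and diffusion.
#' * `activated_macrophage_rhs()`: natural decay, production by activation,
#'   diffusion, and the signed lymph-vessel flux
#'   `-alpha_MA * theta_LV * (M_A - M_A_L)` to the lymph node.
#' * `antibody_rhs()`: consumption by opsonization, diffusion, and the
#'   signed blood-vessel flux `alpha_F * theta_BV * (F_L - F)` from the
#'   lymph node.
#'
#' @param tissue an `imm_tissue` state (see [initial_state()]).
#' @param lymph an `imm_lymph` state (needed where the node couples in).
#' @param params an [default_parameters()] set.
#' @param grid an [grid_spec()].
#' @param vessels an [build_vessel_map()] result.
#' @return a 3D array of derivatives, cells/mm^3 per day.
#' @name tissue_rhs
NULL

#' @rdname tissue_rhs
#' @export
antigen_rhs <- function(tissue, params, grid) {
  A <- tissue$A
  params$beta_A * A * (1 - A / params$k_A) -
    params$mu_A * A -
    params$lambda_MR * tissue$M_R * A -
    params$lambda_MA * A * tissue$M_A -
    params$lambda_AF_MR * A * tissue$F * tissue$M_R -
    params$lambda_AF_MA * A * tissue$F * tissue$M_A +
    params$D_A * laplacian(A, grid)
}

#' @rdname tissue_rhs
#' @export
resting_macrophage_rhs <- function(tissue, params, grid, vessels) {
  M_R <- tissue$M_R
  -params$mu_MR * M_R -
    params$gamma_MA * M_R * tissue$A +
    params$alpha_MR * vessels$theta_BV * (params$MR_star - M_R) +
    params$D_MR * laplacian(M_R, grid)
}

#' @rdname tissue_rhs
#' @export
activated_macrophage_rhs <- function(tissue, lymph, params, grid, vessels) {
  M_A <- tissue$M_A
  -params$mu_MA * M_A +
    params$gamma_MA * tissue$M_R * tissue$A +
    params$D_MA * laplacian(M_A, grid) -
    params$alpha_MA * vessels$theta_LV * (M_A - lymph$M_A_L)
}

#' @rdname tissue_rhs
#' @export
antibody_rhs <- function(tissue, lymph, params, grid, vessels) {
  F <- tissue$F
  -params$lambda_AF_MR * F * tissue$A * tissue$M_R -
    params$lambda_AF_MA * F * tissue$A * tissue$M_A +
    params$D_F * laplacian(F, grid) +
    params$alpha_F * vessels$theta_BV * (lymph$F_L - F)
}
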