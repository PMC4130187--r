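# Grid, vessel geometry and scenario initial conditions.

#' Uniform 3D simulation grid
#'
#' The tissue is a regular hexahedral grid of `nx * ny * nz` voxels.  The
#' spacings `dx`, `dy`, `dz` enter the diffusion stencil (as `D / dx^2`
#' etc.); `voxel_volume` is the tissue volume represented by one voxel
#' (mm^3) and is used for every volume integral: vessel contact volumes,
#' the total amount of antigen, and the lymph-node coupling ratios
#' `V_LV / V_LN` and `V_BV / V_LN`.  The default grid is 10 x 10 x 10
#' voxels with stencil spacing 0.1, each voxel standing for 1 mm^3 of
#' tissue (a 1 cm^3 domain).
#'
#' @param nx,ny,nz voxel counts per axis (>= 3; the 7-point stencil needs
#'   interior points).
#' @param dx,dy,dz stencil spacings (> 0, model length units).
#' @param voxel_volume tissue volume per voxel in mm^3 (> 0).
#' @return an object of class `imm_grid`.
#' @examples
#' g <- grid_spec()
#' g$nx
#' @export
grid_spec <- function(nx = 10, ny = 10, nz = 10,
                      dx = 0.1, dy = 0.1, dz = 0.1,
                      voxel_volume = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (any(c(nx, ny, nz) < 3L)) {
    abort("grid must have at least 3 voxels per axis")
  }
  if (any(c(dx, dy, dz) <= 0) || voxel_volume <= 0) {
    abort("dx, dy, dz and voxel_volume must be positive")
  }
  structure(
    list(nx = nx, ny = ny, nz = nz, dx = dx, dy = dy, dz = dz,
         voxel_volume = voxel_volume),
    class = "imm_grid"
  )
}

#' @export
print.imm_grid <- function(x, ...) {
  cat(sprintf("<imm_grid> %d x %d x %d voxels, spacing (%g, %g, %g), %g mm^3/voxel\n",
              x$nx, x$ny, x$nz, x$dx, x$dy, x$dz, x$voxel_volume))
  invisible(x)
}

grid_dims <- function(grid) c(grid$nx, grid$ny, grid$nz)

zero_field <- function(grid) array(0, dim = grid_dims(grid))

#' Vessel layout descriptor
#'
#' Describes where blood and lymph capillaries run through the tissue.
#' Each capillary is a column of voxels spanning the full y-axis at a fixed
#' (x, z) position (1-based indices).  The default mirrors the published
#' geometry: four blood capillaries on the four (x, z) corner edges of the
#' cube and four lymph capillaries near (but not at) the centre, at
#' (x, z) in {(4, 4), (4, 7), (7, 4), (7, 7)} on the default 10^3 grid.
#'
#' @param blood_xz,lymph_xz two-column integer matrices of (x, z) positions,
#'   one row per capillary, or `NULL` for the default layout.
#' @return an object of class `imm_vessel_layout`.
#' @export
vessel_layout <- function(blood_xz = NULL, lymph_xz = NULL) {
  as_xz <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- matrix(as.integer(m), ncol = 2)
    if (ncol(m) != 2) abort(paste0(what, "_xz must have two columns (x, z)"))
    m
  }
  structure(
    list(blood_xz = as_xz(blood_xz, "blood"),
         lymph_xz = as_xz(lymph_xz, "lymph")),
    class = "imm_vessel_layout"
  )
}

default_blood_xz <- function(grid) {
  rbind(c(1L, 1L), c(1L, grid$nz), c(grid$nx, 1L), c(grid$nx, grid$nz))
}

default_lymph_xz <- function(grid) {
  # interior positions near the centre, offset so the columns do not sit on
  # the exact midplane (visualization convention of the published geometry)
  lo <- function(n) as.integer(floor(0.3 * n)) + 1L
  hi <- function(n) as.integer(floor(0.6 * n)) + 1L
  x <- c(lo(grid$nx), hi(grid$nx)); z <- c(lo(grid$nz), hi(grid$nz))
  as.matrix(expand.grid(x = x, z = z))[, c("x", "z"), drop = FALSE]
}

#' Build blood- and lymph-vessel indicator fields
#'
#' Converts a [vessel_layout()] into binary indicator fields
#' `theta_BV` (blood) and `theta_LV` (lymph) on the grid, and the contact
#' volumes `V_BV = sum(theta_BV) * voxel_volume` and
#' `V_LV = sum(theta_LV) * voxel_volume`.
#'
#' @param grid an [grid_spec()] object.
#' @param layout an [vessel_layout()]; `NULL` gives the default layout.
#' @return an object of class `imm_vessels` with fields `theta_BV`,
#'   `theta_LV` (0/1 arrays) and scalars `V_BV`, `V_LV`.
#' @examples
#' v <- build_vessel_map(grid_spec())
#' v$V_BV  # 4 columns x 10 voxels x 1 mm^3
#' @export
build_vessel_map <- function(grid, layout = NULL) {
  stopifnot(inherits(grid, "imm_grid"))
  if (is.null(layout)) layout <- vessel_layout()
  stopifnot(inherits(layout, "imm_vessel_layout"))
  blood <- layout$blood_xz %||% default_blood_xz(grid)
  lymph <- layout$lymph_xz %||% default_lymph_xz(grid)

  mark <- function(xz, what) {
    th <- zero_field(grid)
    if (nrow(xz) == 0) return(th)
    if (any(xz[, 1] < 1 | xz[, 1] > grid$nx |
            xz[, 2] < 1 | xz[, 2] > grid$nz)) {
      abort(paste0(what, " vessel column outside the grid"))
    }
    for (r in seq_len(nrow(xz))) {
      th[xz[r, 1], , xz[r, 2]] <- 1
    }
    th
  }
  theta_BV <- mark(blood, "blood")
  theta_LV <- mark(lymph, "lymph")
  structure(
    list(theta_BV = theta_BV, theta_LV = theta_LV,
         V_BV = sum(theta_BV) * grid$voxel_volume,
         V_LV = sum(theta_LV) * grid$voxel_volume),
    class = "imm_vessels"
  )
}

#' @export
print.imm_vessels <- function(x, ...) {
  cat(sprintf("<imm_vessels> V_BV = %g, V_LV = %g (%d / %d voxels)\n",
              x$V_BV, x$V_LV, sum(x$theta_BV), sum(x$theta_LV)))
  invisible(x)
}

#' Voxel indices of the central antigen-injection block
#'
#' The initial antigen bolus occupies the central 40% of the index range on
#' each axis: voxel i (0-based) is inside when `0.3 <= i/n < 0.7`.  On the
#' default 10-voxel axis this is 1-based indices 4-7, so the block is the
#' central 4 x 4 x 4 = 64 voxels, away from all boundary faces.
#'
#' @param n number of voxels along the axis.
#' @return 1-based indices of the block along that axis.
#' @export
injection_indices <- function(n) {
  i <- 0:(n - 1)
  which(i / n >= 0.3 & i / n < 0.7)
}

#' Scenario initial state
#'
#' Builds the tissue fields and lymph-node scalars at day 0.  Antigen `A`
#' equals `A0` inside the central injection block and 0 elsewhere; resting
#' macrophages `M_R` equal `MR0` uniformly; activated macrophages and
#' antibodies start at 0, as do all lymph-node variables.  Scenario
#' `"case1"` (antigen only) zeroes `MR0` so the tissue holds no immune
#' cells at all.
#'
#' @param grid an [grid_spec()].
#' @param params an [default_parameters()] set.
#' @param scenario one of `"case1"`, `"case2"`, `"case3"`.
#' @return a list with elements `tissue` (class `imm_tissue`: arrays `A`,
#'   `M_R`, `M_A`, `F`) and `lymph` (class `imm_lymph`: scalars `M_A_L`,
#'   `T`, `B`, `P`, `F_L`).
#' @export
initial_state <- function(grid, params = default_parameters(),
                          scenario = c("case3", "case1", "case2")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(grid, "imm_grid"), inherits(params, "imm_params"))
  A <- zero_field(grid)
  ix <- injection_indices(grid$nx)
  iy <- injection_indices(grid$ny)
  iz <- injection_indices(grid$nz)
  A[ix, iy, iz] <- params$A0
  mr0 <- if (scenario == "case1") 0 else params$MR0
  tissue <- structure(
    list(A = A,
         M_R = array(mr0, dim = grid_dims(grid)),
         M_A = array(params$MA0, dim = grid_dims(grid)),
         F = array(params$F0, dim = grid_dims(grid))),
    class = "imm_tissue"
  )
  lymph <- structure(
    list(M_A_L = params$MA0, T = params$T0, B = params$B0,
         P = params$P0, F_L = params$FL0),
    class = "imm_lymph"
  )
  list(tissue = tissue, lymph = lymph)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
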