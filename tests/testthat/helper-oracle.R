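# Scalar, triple-loop re-implementations of the discrete operators.
# Deliberately naive and independent of the vectorized/compiled paths they
# are used to check.

oracle_laplacian <- function(f, grid) {
  d <- dim(f)
  out <- array(0, d)
  cl <- function(i, n) min(max(i, 1L), n)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    out[i, j, k] <-
      (f[cl(i + 1, d[1]), j, k] - 2 * f[i, j, k] + f[cl(i - 1, d[1]), j, k]) / grid$dx^2 +
      (f[i, cl(j + 1, d[2]), k] - 2 * f[i, j, k] + f[i, cl(j - 1, d[2]), k]) / grid$dy^2 +
      (f[i, j, cl(k + 1, d[3])] - 2 * f[i, j, k] + f[i, j, cl(k - 1, d[3])]) / grid$dz^2
  }
  out
}

# pointwise reaction terms evaluated voxel by voxel from the equations
oracle_rhs <- function(tissue, lymph, p, grid, vessels) {
  d <- dim(tissue$A)
  lapA <- oracle_laplacian(tissue$A, grid)
  lapMR <- oracle_laplacian(tissue$M_R, grid)
  lapMA <- oracle_laplacian(tissue$M_A, grid)
  lapF <- oracle_laplacian(tissue$F, grid)
  dA <- dMR <- dMA <- dF <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    A <- tissue$A[i, j, k]; MR <- tissue$M_R[i, j, k]
    MA <- tissue$M_A[i, j, k]; F <- tissue$F[i, j, k]
    bv <- vessels$theta_BV[i, j, k]; lv <- vessels$theta_LV[i, j, k]
    dA[i, j, k] <- p$beta_A * A * (1 - A / p$k_A) - p$mu_A * A -
      p$lambda_MR * MR * A - p$lambda_MA * A * MA -
      p$lambda_AF_MR * A * F * MR - p$lambda_AF_MA * A * F * MA +
      p$D_A * lapA[i, j, k]
    dMR[i, j, k] <- -p$mu_MR * MR - p$gamma_MA * MR * A +
      p$alpha_MR * bv * (p$MR_star - MR) + p$D_MR * lapMR[i, j, k]
    dMA[i, j, k] <- -p$mu_MA * MA + p$gamma_MA * MR * A +
      p$D_MA * lapMA[i, j, k] - p$alpha_MA * lv * (MA - lymph$M_A_L)
    dF[i, j, k] <- -p$lambda_AF_MR * F * A * MR - p$lambda_AF_MA * F * A * MA +
      p$D_F * lapF[i, j, k] + p$alpha_F * bv * (lymph$F_L - F)
  }
  list(dA = dA, dM_R = dMR, dM_A = dMA, dF = dF)
}

# random small test states
random_tissue <- function(grid, scale = c(A = 5, M_R = 4, M_A = 2, F = 3)) {
  d <- c(grid$nx, grid$ny, grid$nz)
  structure(
    list(A = array(stats::runif(prod(d), 0, scale["A"]), d),
         M_R = array(stats::runif(prod(d), 0, scale["M_R"]), d),
         M_A = array(stats::runif(prod(d), 0, scale["M_A"]), d),
         F = array(stats::runif(prod(d), 0, scale["F"]), d)),
    class = "imm_tissue"
  )
}

random_lymph <- function() {
  structure(
    list(M_A_L = stats::runif(1, 0, 2), T = stats::runif(1, 0, 0.01),
         B = stats::runif(1, 0, 0.001), P = stats::runif(1, 0, 1e-4),
         F_L = stats::runif(1, 0, 50)),
    class = "imm_lymph"
  )
}

small_grid <- function(n = 3, ...) grid_spec(n, n, n, ...)

small_vessels <- function(grid) {
  build_vessel_map(grid, vessel_layout(
    blood_xz = rbind(c(1, 1), c(grid$nx, grid$nz)),
    lymph_xz = rbind(c(2, 2))
  ))
}
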