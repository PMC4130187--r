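test_that("antigen rhs: zeros, uniform decay, logistic-decay fixed point", {
  g <- small_grid(4)
  p <- default_parameters()
  zero <- array(0, c(4, 4, 4))
  mk <- function(A) structure(list(A = A, M_R = zero, M_A = zero, F = zero),
                              class = "imm_tissue")
  # A == 0 -> every term vanishes
  expect_true(all(antigen_rhs(mk(zero), p, g) == 0))
  # uniform A = k_A: logistic term vanishes, only decay remains
  expect_equal(antigen_rhs(mk(array(50, c(4, 4, 4))), p, g),
               array(-5, c(4, 4, 4)))
  # uniform A = k_A (1 - mu_A / beta_A) = 47.5 is a fixed point
  expect_equal(antigen_rhs(mk(array(47.5, c(4, 4, 4))), p, g),
               zero, tolerance = 1e-12)
})

test_that("resting macrophage rhs: vessel source and decay balance", {
  g <- small_grid(4)
  p <- default_parameters()
  v <- small_vessels(g)
  zero <- array(0, c(4, 4, 4))
  mk <- function(MR) structure(list(A = zero, M_R = MR, M_A = zero, F = zero),
                               class = "imm_tissue")
  # M_R at its blood steady level: source vanishes, decay -mu_MR * 4 everywhere
  r <- resting_macrophage_rhs(mk(array(4, c(4, 4, 4))), p, g, v)
  expect_equal(r, array(-0.132, c(4, 4, 4)))
  # empty tissue: influx alpha_MR * MR_star = 16 at vessel voxels only
  r0 <- resting_macrophage_rhs(mk(zero), p, g, v)
  expect_equal(r0, 16 * v$theta_BV)
  expect_true(all(r0 >= 0))
})

test_that("activated macrophage rhs: lymph flux is signed", {
  g <- small_grid(4)
  p <- default_parameters()
  v <- small_vessels(g)
  zero <- array(0, c(4, 4, 4))
  lymph0 <- structure(list(M_A_L = 0, T = 0, B = 0, P = 0, F_L = 0),
                      class = "imm_lymph")
  t0 <- structure(list(A = zero, M_R = zero, M_A = zero, F = zero),
                  class = "imm_tissue")
  expect_true(all(activated_macrophage_rhs(t0, lymph0, p, g, v) == 0))
  # uniform M_A equal to the node concentration: flux term vanishes
  m <- 1.7
  tm <- structure(list(A = zero, M_R = zero, M_A = array(m, c(4, 4, 4)),
                       F = zero), class = "imm_tissue")
  lm <- structure(list(M_A_L = m, T = 0, B = 0, P = 0, F_L = 0),
                  class = "imm_lymph")
  expect_equal(activated_macrophage_rhs(tm, lm, p, g, v),
               array(-p$mu_MA * m, c(4, 4, 4)))
  # node richer than tissue: back-flow is positive at lymph voxels
  lr <- structure(list(M_A_L = 10, T = 0, B = 0, P = 0, F_L = 0),
                  class = "imm_lymph")
  r <- activated_macrophage_rhs(t0, lr, p, g, v)
  expect_true(all(r[v$theta_LV == 1] > 0))
  expect_true(all(r[v$theta_LV == 0] == 0))
})

test_that("antibody rhs: influx only through blood vessels", {
  g <- small_grid(4)
  p <- default_parameters()
  v <- small_vessels(g)
  zero <- array(0, c(4, 4, 4))
  t0 <- structure(list(A = zero, M_R = zero, M_A = zero, F = zero),
                  class = "imm_tissue")
  l0 <- structure(list(M_A_L = 0, T = 0, B = 0, P = 0, F_L = 0),
                  class = "imm_lymph")
  expect_true(all(antibody_rhs(t0, l0, p, g, v) == 0))
  lf <- structure(list(M_A_L = 0, T = 0, B = 0, P = 0, F_L = 12),
                  class = "imm_lymph")
  r <- antibody_rhs(t0, lf, p, g, v)
  expect_equal(r, p$alpha_F * 12 * v$theta_BV)
  # equal concentrations, no antigen: nothing happens
  tf <- structure(list(A = zero, M_R = array(4, c(4, 4, 4)), M_A = zero,
                       F = array(12, c(4, 4, 4))), class = "imm_tissue")
  lq <- structure(list(M_A_L = 0, T = 0, B = 0, P = 0, F_L = 12),
                  class = "imm_lymph")
  expect_true(all(antibody_rhs(tf, lq, p, g, v) == 0))
})

test_that("all four rhs match the scalar-loop oracle on random states", {
  set.seed(101)
  for (rep in 1:3) {
    g <- small_grid(3)
    v <- small_vessels(g)
    p <- default_parameters()
    tissue <- random_tissue(g)
    lymph <- random_lymph()
    o <- oracle_rhs(tissue, lymph, p, g, v)
    expect_equal(antigen_rhs(tissue, p, g), o$dA, tolerance = 1e-12)
    expect_equal(resting_macrophage_rhs(tissue, p, g, v), o$dM_R,
                 tolerance = 1e-12)
    expect_equal(activated_macrophage_rhs(tissue, lymph, p, g, v), o$dM_A,
                 tolerance = 1e-12)
    expect_equal(antibody_rhs(tissue, lymph, p, g, v), o$dF,
                 tolerance = 1e-12)
  }
})

test_that("each rhs is local up to the 7-point stencil", {
  set.seed(5)
  g <- grid_spec(5, 5, 5)
  v <- small_vessels(g)
  p <- default_parameters()
  lymph <- random_lymph()
  t1 <- random_tissue(g)
  t2 <- t1
  t2$A[3, 3, 3] <- t2$A[3, 3, 3] + 1
  d <- abs(antigen_rhs(t2, p, g) - antigen_rhs(t1, p, g))
  changed <- which(d > 0, arr.ind = TRUE)
  dist <- abs(changed - matrix(3, nrow(changed), 3))
  expect_true(all(rowSums(dist) <= 1))  # voxel itself or a face neighbour
})
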