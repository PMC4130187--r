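zero_params <- function(...) {
  # all rates zero except explicit overrides: isolates single mechanisms
  p <- default_parameters()
  for (nm in names(p)) p[[nm]] <- 0
  p$k_A <- 50; p$V_LN <- 160
  p <- validate_parameters(p)
  do.call(modify_parameters, c(list(p), list(...)))
}

test_that("the homeostatic lymph state is an exact fixed point of stepping", {
  g <- small_grid(4)
  v <- small_vessels(g)
  p <- default_parameters()
  st <- initial_state(g, p, "case3")
  tissue <- st$tissue
  tissue$A[] <- 0  # no antigen, no resting macrophages
  tissue$M_R[] <- 0
  lymph <- structure(list(M_A_L = 0, T = p$T_star, B = p$B_star, P = p$P_star,
                          F_L = 0), class = "imm_lymph")
  lymph0 <- lymph
  # F_L grows by rho_F * P_star, everything else must stay put exactly;
  # hold P at its steady level and zero the release to get a full fixed point
  p2 <- modify_parameters(p, rho_F = 0)
  for (i in 1:25) {
    s <- euler_step(tissue, lymph, p2, g, v, 1e-3)
    tissue <- s$tissue; lymph <- s$lymph
  }
  expect_identical(lymph$T, lymph0$T)
  expect_identical(lymph$B, lymph0$B)
  expect_identical(lymph$P, lymph0$P)
  expect_identical(lymph$M_A_L, 0)
  expect_true(all(tissue$A == 0) && all(tissue$M_A == 0))
})

test_that("uniform antigen at the logistic-decay fixed point stays put", {
  g <- small_grid(4)
  v <- small_vessels(g)
  p <- modify_parameters(default_parameters(),
                         MR0 = 0, alpha_MR = 0, alpha_MA = 0, alpha_F = 0)
  zero <- array(0, c(4, 4, 4))
  tissue <- structure(list(A = array(47.5, c(4, 4, 4)), M_R = zero,
                           M_A = zero, F = zero), class = "imm_tissue")
  lymph <- structure(list(M_A_L = 0, T = 0, B = 0, P = 0, F_L = 0),
                     class = "imm_lymph")
  for (i in 1:50) tissue <- euler_step(tissue, lymph, p, g, v, 1e-4)$tissue
  expect_equal(tissue$A, array(47.5, c(4, 4, 4)), tolerance = 1e-12)
})

test_that("pure diffusion conserves total mass to round-off", {
  set.seed(31)
  g <- small_grid(5)
  v <- small_vessels(g)
  p <- zero_params(D_A = 1e-3, D_MR = 2e-3, D_MA = 3e-3, D_F = 0.5e-3)
  tissue <- random_tissue(g)
  lymph <- structure(list(M_A_L = 0, T = 0, B = 0, P = 0, F_L = 0),
                     class = "imm_lymph")
  m0 <- vapply(tissue[c("A", "M_R", "M_A", "F")], sum, numeric(1)) *
    g$voxel_volume
  for (i in 1:200) tissue <- euler_step(tissue, lymph, p, g, v, 1e-4)$tissue
  m1 <- vapply(tissue[c("A", "M_R", "M_A", "F")], sum, numeric(1)) *
    g$voxel_volume
  expect_equal(m1, m0, tolerance = 1e-12)
})

test_that("values driven negative are clamped to zero and counted", {
  g <- small_grid(3)
  v <- small_vessels(g)
  # huge decay rate forces overshoot in one Euler step
  p <- zero_params(mu_A = 3e4)
  zero <- array(0, c(3, 3, 3))
  tissue <- structure(list(A = array(1, c(3, 3, 3)), M_R = zero, M_A = zero,
                           F = zero), class = "imm_tissue")
  lymph <- structure(list(M_A_L = 0, T = 0, B = 0, P = 0, F_L = 0),
                     class = "imm_lymph")
  s <- euler_step(tissue, lymph, p, g, v, 1e-3)
  expect_true(all(s$tissue$A == 0))
  expect_identical(as.integer(s$clamped), 27L)
})

test_that("compiled engine reproduces the R reference engine exactly", {
  g <- small_grid(4)
  cfg <- simulation_config("case3", grid = g,
                           layout = vessel_layout(
                             blood_xz = rbind(c(1, 1), c(4, 4)),
                             lymph_xz = rbind(c(2, 2), c(3, 3))),
                           num_days = 2, dt = 1e-3, iter_per_day = 1000,
                           stop_on_tol = FALSE, snapshot_days = c(0, 2))
  r_cpp <- run_simulation(cfg, engine = "cpp")
  r_r <- run_simulation(cfg, engine = "r")
  expect_equal(r_cpp$series, r_r$series, tolerance = 1e-13)
  expect_equal(r_cpp$negative_clamp_count, r_r$negative_clamp_count)
  expect_equal(r_cpp$snapshots[["2"]]$A, r_r$snapshots[["2"]]$A,
               tolerance = 1e-13)
  expect_equal(r_cpp$total_antigen, r_r$total_antigen, tolerance = 1e-13)
})

test_that("non-finite values abort with a diagnostic naming the variable", {
  g <- small_grid(3)
  # overflow the antigen field: gigantic replication with a 1-day step
  cfg <- simulation_config("case2", grid = g,
                           layout = vessel_layout(
                             blood_xz = rbind(c(1, 1)),
                             lymph_xz = rbind(c(2, 2))),
                           num_days = 1, dt = 1, iter_per_day = 1,
                           beta_A = 1e308, k_A = 1e308,
                           D_A = 0, D_MR = 0, D_MA = 0, D_F = 0)
  expect_error(run_simulation(cfg), "non-finite.*A")
})

test_that("mirror-symmetric geometry gives identical averaged series", {
  # reflecting the whole geometry through the x mid-plane must not change
  # any spatial average: the discretization has no directional bias
  g <- grid_spec()  # injection block 4:7 is mirror-symmetric on 10 voxels
  refl <- function(x) g$nx + 1L - x
  lay1 <- vessel_layout(blood_xz = rbind(c(1, 1), c(2, 10)),
                        lymph_xz = rbind(c(3, 3), c(4, 6)))
  lay2 <- vessel_layout(blood_xz = rbind(c(refl(1), 1), c(refl(2), 10)),
                        lymph_xz = rbind(c(refl(3), 3), c(refl(4), 6)))
  mk <- function(lay) {
    run_simulation(simulation_config("case3", grid = g, layout = lay,
                                     num_days = 2, dt = 1e-3,
                                     iter_per_day = 1000,
                                     stop_on_tol = FALSE))
  }
  r1 <- mk(lay1); r2 <- mk(lay2)
  expect_equal(r1$series, r2$series, tolerance = 1e-12)
})
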