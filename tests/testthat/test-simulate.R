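test_that("scenario presets carry the published wiring", {
  c1 <- scenario_preset("case1")
  expect_identical(c1$params$MR0, 0)
  expect_identical(c1$params$alpha_MR, 0)
  expect_identical(c1$num_days, 100L)
  c2 <- scenario_preset("case2")
  expect_identical(c2$params$alpha_MA, 0)
  expect_identical(c2$params$alpha_F, 0)
  expect_identical(c2$params$MR0, 4)
  c3 <- scenario_preset("case3")
  expect_identical(c3$num_days, 30L)
  expect_identical(c3$params$alpha_MA, 1e-3)
  expect_error(scenario_preset("case4"), "unknown scenario")
})

test_that("config construction enforces stepping invariants", {
  expect_error(simulation_config("case3", dt = 1e-4, iter_per_day = 5000),
               "dt \\* iter_per_day")
  # violating the diffusion stability bound is rejected
  expect_error(simulation_config("case3", dt = 1e-2, iter_per_day = 100),
               "unstable")
  expect_error(simulation_config("case3", num_days = 0), "num_days")
})

test_that("case1 leaves the immune system inert", {
  cfg <- scenario_preset("case1", num_days = 2)
  r <- run_simulation(cfg)
  s <- r$series
  expect_true(all(s$MR_avg == 0))
  expect_true(all(s$MA_avg == 0))
  expect_true(all(s$F_avg == 0))
  expect_true(all(s$MAL == 0))
  expect_gt(s$A_avg[nrow(s)], s$A_avg[1])  # unopposed growth
})

test_that("case2 leaves the lymph node decoupled from the tissue", {
  cfg <- scenario_preset("case2", num_days = 2)
  r <- run_simulation(cfg)
  s <- r$series
  expect_true(all(s$MAL == 0))
  expect_true(all(s$F_avg == 0))       # no antibodies without coupling
  expect_gt(s$MA_avg[nrow(s)], 0)      # innate activation is on
  # node homeostasis proceeds on its own
  expect_gt(s$T[nrow(s)], 0)
})

test_that("recording respects the stride and includes day 0 and the last day", {
  cfg <- scenario_preset("case2", num_days = 10, record_stride = 3,
                         stop_on_tol = FALSE)
  r <- run_simulation(cfg)
  expect_identical(r$series$day, c(0L, 3L, 6L, 9L, 10L))
})

test_that("early stopping reports the elimination day and stops there", {
  # strong decay, no replication: antigen dies within a few days
  cfg <- scenario_preset("case1", num_days = 50, beta_A = 0, mu_A = 2)
  r <- run_simulation(cfg)
  expect_identical(r$stopping_reason, "tolerance")
  expect_false(is.na(r$elimination_day))
  expect_lt(r$elimination_day, 50)
  expect_identical(max(r$series$day), r$elimination_day)
  expect_lte(r$total_antigen[length(r$total_antigen)], cfg$tol)
  # the reported day is the first one satisfying the criterion
  below <- r$series$day[r$total_antigen <= cfg$tol]
  expect_identical(min(below), r$elimination_day)
})

test_that("halving the time step leaves the case 3 antigen series unchanged to <1%", {
  r1 <- cached_sim("case3_nostop", function() {
    run_simulation(scenario_preset("case3", stop_on_tol = FALSE))
  })
  r2 <- cached_sim("case3_dthalf", function() {
    run_simulation(simulation_config("case3", dt = 5e-5, iter_per_day = 2e4,
                                     stop_on_tol = FALSE))
  })
  a1 <- r1$series$A_avg[r1$series$day == 30]
  a2 <- r2$series$A_avg[r2$series$day == 30]
  expect_lt(abs(a1 - a2) / abs(a1), 0.01)
})

test_that("a stronger antibody migration rate never delays elimination", {
  elim <- vapply(c(0.215, 0.43, 0.86), function(af) {
    key <- paste0("case3_aF_", af)
    r <- cached_sim(key, function() {
      run_simulation(scenario_preset("case3", alpha_F = af))
    })
    if (is.na(r$elimination_day)) Inf else as.numeric(r$elimination_day)
  }, numeric(1))
  expect_true(all(diff(elim) <= 0))
})

test_that("published time step produces no negative overshoot in any scenario", {
  expect_identical(sim_case1_100()$negative_clamp_count, 0)
  expect_identical(sim_case2_100()$negative_clamp_count, 0)
  expect_identical(sim_case3()$negative_clamp_count, 0)
})

test_that("tidy and glance summarise a run", {
  r <- cached_sim("case2_short", function() {
    run_simulation(scenario_preset("case2", num_days = 3))
  })
  td <- tidy(r)
  expect_identical(names(td), c("day", "compartment", "value"))
  expect_identical(nrow(td), nrow(r$series) * 9L)
  gl <- glance(r)
  expect_identical(gl$scenario, "case2")
  expect_identical(gl$days_simulated, 3L)
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
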