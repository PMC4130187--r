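# Shared cache for the long scenario runs used by several test files, so
# each configuration is simulated at most once per test session.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

sim_case1_100 <- function() {
  cached_sim("case1_100", function() run_simulation(scenario_preset("case1")))
}

sim_case2_100 <- function() {
  cached_sim("case2_100", function() run_simulation(scenario_preset("case2")))
}

sim_case3 <- function() {
  cached_sim("case3", function() run_simulation(scenario_preset("case3")))
}

sim_case3_nostop <- function() {
  cached_sim("case3_nostop", function() {
    run_simulation(scenario_preset("case3", stop_on_tol = FALSE))
  })
}

peak_day <- function(sim, var) {
  sim$series$day[which.max(sim$series[[var]])]
}
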