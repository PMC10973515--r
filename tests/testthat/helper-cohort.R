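# The full-size synthetic cohort (11 patients, ~30,000 cells) is expensive
# to simulate, and several test files interrogate it; build it once per
# test session.
.cohort_env <- new.env(parent = emptyenv())

main_cohort <- function() {
  if (is.null(.cohort_env$res))
    .cohort_env$res <- suppressMessages(run_recovery_cohort(seed = 101))
  .cohort_env$res
}

main_sim <- function() {
  if (is.null(.cohort_env$sim))
    .cohort_env$sim <- simulate_cells(sim_config(seed = 101))
  .cohort_env$sim
}
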