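# shared fixtures; expensive optimal-control solves are cached per test run
# so several test blocks can interrogate the same converged solution

fix_load <- function(...) default_load(...)
fix_muscle <- function(...) default_muscle(...)

.solution_cache <- new.env(parent = emptyenv())

cached_solution <- function(key, make) {
  if (is.null(.solution_cache[[key]])) .solution_cache[[key]] <- make()
  .solution_cache[[key]]
}

single_solution_2p4 <- function() {
  cached_solution("single_2p4", function() {
    solve_cyclic_optimal_control(ocp(fix_muscle(), fix_load(), 2.4))
  })
}

pair_solution_2p4 <- function() {
  cached_solution("pair_2p4", function() {
    solve_cyclic_optimal_control(
      ocp(list(fix_muscle(), fix_muscle()), fix_load(), 2.4))
  })
}

# analytic two-pole cascade step response (independent closed form)
cascade_step <- function(t, tau) 1 - (1 + t / tau) * exp(-t / tau)

# local trapezoid rule (kept independent of the package internals)
trapz_test <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
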