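# Shared fixtures and independent oracles for the test suite.

acq0 <- asl_acq()

# central finite difference of a scalar-parameter function
fd_central <- function(fun, x, h) (fun(x + h) - fun(x - h)) / (2 * h)

# brute-force 2x2 Fisher information by explicit outer-product summation,
# with sensitivities from finite differences of the signal model
fim_bruteforce <- function(times, cbf, att, acq, n_averages = 1,
                           noise_variance = 1) {
  F <- matrix(0, 2, 2)
  for (t in times) {
    s_cbf <- fd_central(function(x) {
      gkm_signal(t, x, att, acq, t1prime_mode = "fixed")
    }, cbf, 1e-4)
    s_att <- fd_central(function(x) {
      gkm_signal(t, cbf, x, acq, t1prime_mode = "fixed")
    }, att, 1e-6)
    s <- c(s_cbf, s_att)
    F <- F + s %o% s
  }
  F * n_averages / noise_variance
}

# exhaustive search over all monotone PLD pairs on a coarse grid
exhaustive_pair_search <- function(prior, spec, acq, grid,
                                   scan_time_budget = 300) {
  best <- NULL
  best_cost <- Inf
  for (i in seq_along(grid)) {
    for (j in i:length(grid)) {
      pro <- asl_protocol(c(grid[i], grid[j]), n_slices = 1,
                          slice_duration = 0,
                          scan_time_budget = scan_time_budget)
      if (pro$n_averages < 1) next
      cost <- tryCatch(expected_cost(pro, prior, spec, acq),
                       error = function(e) Inf)
      if (cost < best_cost) {
        best_cost <- cost
        best <- c(grid[i], grid[j])
      }
    }
  }
  list(plds = best, cost = best_cost)
}
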