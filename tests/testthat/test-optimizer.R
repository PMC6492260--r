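test_that("expected cost reduces to the single-FIM criterion for a point prior", {
  pp <- att_prior_weights(1.0, 1)
  pro <- asl_protocol(c(0.5, 1.0, 1.5), n_slices = 1, slice_duration = 0)
  for (kind in c("d_optimal", "l_optimal")) {
    spec <- criterion_spec(kind)
    tms <- pro$label_duration + pro$plds
    direct <- criterion_value(build_fim(tms, 50, 1.0, acq0,
                                        n_averages = pro$n_averages),
                              spec)
    expect_equal(expected_cost(pro, pp, spec, acq0), direct)
  }
})

test_that("expected cost scales with noise and collapses degenerate geometry", {
  prior <- att_prior(0.8, 1.4, taper = 0, step = 0.1)
  pro <- asl_protocol(c(0.5, 1.0, 1.5), n_slices = 1, slice_duration = 0)
  spec <- criterion_spec("l_optimal")
  c1 <- expected_cost(pro, prior, spec, acq0, noise_variance = 1)
  c5 <- expected_cost(pro, prior, spec, acq0, noise_variance = 5)
  expect_equal(c5, 5 * c1)
  # two slices with zero slice duration see identical times: same cost
  pro2 <- asl_protocol(c(0.5, 1.0, 1.5), n_slices = 2, slice_duration = 0)
  expect_equal(expected_cost(pro2, prior, spec, acq0), c1)
  # zero-average protocol is infeasible
  tiny <- asl_protocol(c(0.5, 1.0, 1.5), scan_time_budget = 10)
  expect_error(expected_cost(tiny, prior, spec, acq0),
               class = "asl_infeasible_design")
})

test_that("exchange search matches exhaustive enumeration for two delays", {
  prior <- att_prior(0.7, 1.3, taper = 0, step = 0.1)
  grid <- seq(0.2, 3, by = 0.1)
  for (kind in c("d_optimal", "l_optimal")) {
    spec <- criterion_spec(kind)
    oracle <- exhaustive_pair_search(prior, spec, acq0, grid)
    found <- optimize_plds(2, prior, spec, acq0, n_slices = 1,
                           slice_duration = 0, pld_step = 0.1)
    expect_equal(found$plds, oracle$plds)
    expect_equal(attr(found, "optimization")$cost, oracle$cost)
  }
})

test_that("point-prior designs sample the arrival and the bolus peak", {
  # sample times cluster at t = ATT (arrival, peak ATT information) and
  # t = ATT + tau (bolus peak, peak CBF information), i.e. delays at
  # max(ATT - tau, pld_min) and ATT
  for (a in c(1.0, 1.8)) {
    pp <- att_prior_weights(a, 1)
    o <- optimize_plds(6, pp, criterion_spec("d_optimal"), acq0,
                       n_slices = 1, slice_duration = 0,
                       init_range = c(0.25, min(2.5, a + 0.5)))
    centers <- c(max(a - acq0$label_duration, 0.2), a)
    dist <- vapply(o$plds, function(p) min(abs(p - centers)), numeric(1))
    expect_true(all(dist <= 0.051))
    # both clusters are used
    nearest <- vapply(o$plds, function(p) which.min(abs(p - centers)),
                      integer(1))
    expect_setequal(unique(nearest), c(1L, 2L))
  }
})

test_that("optimized designs are invariant to the CBF point prior", {
  prior <- att_prior(step = 0.01)
  o30 <- optimize_plds(6, prior, criterion_spec("d_optimal"), acq0,
                       cbf_point = 30)
  o70 <- optimize_plds(6, prior, criterion_spec("d_optimal"), acq0,
                       cbf_point = 70)
  expect_identical(o30$plds, o70$plds)
})

test_that("exchange passes improve monotonically and respect the budget", {
  prior <- att_prior(step = 0.005)
  o <- optimize_plds(8, prior, criterion_spec("d_optimal"), acq0)
  info <- attr(o, "optimization")
  expect_true(all(diff(info$cost_trace) <= 1e-9 * info$cost_trace[-1]))
  expect_true(info$converged)
  expect_gte(o$n_averages, 1)
  expect_lte(scan_time(o), o$scan_time_budget)
  expect_equal(o$plds, sort(o$plds))
  # the longest chosen delay never exceeds the longest prior transit time
  expect_lte(max(o$plds), max(prior$att))
})

test_that("final cost is insensitive to range-covering initializations", {
  prior <- att_prior(step = 0.005)
  costs <- vapply(list(c(0.25, 1.5), c(0.3, 1.6), c(0.2, 1.4)),
                  function(rg) {
    o <- optimize_plds(8, prior, criterion_spec("d_optimal"), acq0,
                       init_range = rg)
    attr(o, "optimization")$cost
  }, numeric(1))
  expect_lt(diff(range(costs)) / min(costs), 0.005)
})

test_that("delay-count sweep reports every requested count", {
  prior <- att_prior(0.8, 1.4, taper = 0, step = 0.05)
  single <- sweep_num_plds(4, prior, spec = criterion_spec("d_optimal"),
                           acq = acq0, n_slices = 1, slice_duration = 0)
  direct <- optimize_plds(4, prior, criterion_spec("d_optimal"), acq0,
                          n_slices = 1, slice_duration = 0)
  expect_equal(single$best$plds, direct$plds)
  sw <- sweep_num_plds(c(3, 4, 5), prior,
                       spec = criterion_spec("d_optimal"), acq = acq0,
                       n_slices = 1, slice_duration = 0)
  expect_length(sw$costs, 3)
  expect_true(all(is.finite(sw$costs)))
  expect_equal(sw$costs[[as.character(sw$best_n)]], min(sw$costs))
})
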