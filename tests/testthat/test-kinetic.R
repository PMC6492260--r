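test_that("apparent T1 follows the outflow-corrected relaxation rate", {
  expect_equal(apparent_t1(0, acq0), acq0$t1_tissue)
  f50 <- cbf_to_rate(50)
  expect_equal(apparent_t1(f50, acq0), 1 / (1 / 1.445 + (50 / 6000) / 0.9))
  expect_equal(round(apparent_t1(f50, acq0), 4), 1.4259)
  # strictly decreasing in flow
  fs <- cbf_to_rate(c(10, 20, 40, 80))
  expect_true(all(diff(apparent_t1(fs, acq0)) < 0))
  expect_error(apparent_t1(-0.01, acq0), class = "asl_invalid_parameter")
})

test_that("kinetic curve is piecewise with the expected phases", {
  expect_equal(gkm_signal(0.3, 50, 0.5, acq0), 0)  # pre-arrival
  expect_equal(gkm_signal(seq(0, 5, 0.25), 0, 0.5, acq0),
               rep(0, 21))  # zero perfusion
  # plateau value at t = tau + att against direct evaluation of the model
  t1p <- apparent_t1(cbf_to_rate(50), acq0)
  plateau <- 2 * (50 / 6000) * t1p * 0.85 * exp(-0.5 / 1.65) *
    (1 - exp(-1.4 / t1p))
  expect_equal(gkm_signal(1.9, 50, 0.5, acq0), plateau)
  expect_equal(plateau, 9.33e-3, tolerance = 1e-3)
  expect_error(gkm_signal(-0.1, 50, 0.5, acq0),
               class = "asl_invalid_parameter")
})

test_that("kinetic curve is continuous at both breakpoints and peaks at tau+att", {
  set.seed(4)
  for (i in 1:10) {
    cbf <- runif(1, 10, 90)
    att <- runif(1, 0.3, 2)
    for (mode in c("self", "fixed")) {
      eps <- 1e-9
      at_arrival <- gkm_signal(c(att - eps, att + eps), cbf, att, acq0,
                               t1prime_mode = mode)
      expect_lt(abs(diff(at_arrival)), 1e-10)
      peak_t <- acq0$label_duration + att
      at_peak <- gkm_signal(c(peak_t - eps, peak_t + eps), cbf, att, acq0,
                            t1prime_mode = mode)
      expect_lt(abs(diff(at_peak)), 1e-10)
    }
    tg <- seq(0, 6, by = 0.002)
    sig <- gkm_signal(tg, cbf, att, acq0)
    expect_lt(abs(tg[which.max(sig)] - (acq0$label_duration + att)), 0.0025)
  }
})

test_that("signal is linear in M0B and, with frozen T1', in perfusion", {
  tg <- seq(0.2, 5, by = 0.1)
  a2 <- asl_acq(m0_blood = 3.7)
  expect_equal(gkm_signal(tg, 50, 0.8, a2), 3.7 * gkm_signal(tg, 50, 0.8, acq0))
  s1 <- gkm_signal(tg, 20, 0.8, acq0, t1prime_mode = "fixed")
  s2 <- gkm_signal(tg, 60, 0.8, acq0, t1prime_mode = "fixed")
  expect_equal(s2, 3 * s1)
})

test_that("sensitivity functions match finite-difference oracles", {
  set.seed(11)
  for (i in 1:8) {
    cbf <- runif(1, 5, 95)
    att <- runif(1, 0.3, 1.9)
    # time grid avoiding the immediate vicinity of the breakpoints
    tg <- c(att / 2, att + c(0.11, 0.52, 0.9) * acq0$label_duration,
            att + acq0$label_duration + c(0.2, 0.8, 1.6))
    tg <- tg[abs(tg - att) > 0.05 &
               abs(tg - att - acq0$label_duration) > 0.05]

    simp <- cbf_sensitivity_simplified(tg, att, acq0)
    fd_simp <- vapply(tg, function(t) {
      fd_central(function(x) {
        gkm_signal(t, rate_to_cbf(x), att, acq0, t1prime_mode = "fixed")
      }, cbf_to_rate(cbf), 1e-5)
    }, numeric(1))
    expect_equal(simp, fd_simp, tolerance = 1e-6)

    comp <- cbf_sensitivity_complete(tg, cbf, att, acq0)
    fd_comp <- vapply(tg, function(t) {
      fd_central(function(x) {
        gkm_signal(t, rate_to_cbf(x), att, acq0, t1prime_mode = "self")
      }, cbf_to_rate(cbf), 1e-6)
    }, numeric(1))
    expect_equal(comp, fd_comp, tolerance = 1e-6)

    for (mode in c("fixed", "self")) {
      sa <- att_sensitivity(tg, cbf, att, acq0, t1prime_mode = mode)
      fd_att <- vapply(tg, function(t) {
        fd_central(function(x) {
          gkm_signal(t, cbf, x, acq0, t1prime_mode = mode)
        }, att, 1e-6)
      }, numeric(1))
      expect_equal(sa, fd_att, tolerance = 1e-5)
    }
  }
})

test_that("sensitivity identities hold", {
  tg <- seq(0.1, 5, by = 0.1)
  att <- 0.6
  # zero before arrival
  expect_equal(cbf_sensitivity_simplified(tg[tg < att], att, acq0),
               rep(0, sum(tg < att)))
  expect_equal(att_sensitivity(tg[tg < att], 50, att, acq0),
               rep(0, sum(tg < att)))
  # f * simplified sensitivity reproduces the frozen-T1' signal
  expect_equal(cbf_to_rate(37) * cbf_sensitivity_simplified(tg, att, acq0),
               gkm_signal(tg, 37, att, acq0, t1prime_mode = "fixed"))
  # transit-time sensitivity is proportional to perfusion
  expect_equal(att_sensitivity(tg, 80, att, acq0),
               2 * att_sensitivity(tg, 40, att, acq0))
  # with no outflow reference flow, complete at f=0 equals simplified
  a0 <- asl_acq(fixed_outflow_cbf = 0)
  expect_equal(cbf_sensitivity_complete(tg, 0, att, a0),
               cbf_sensitivity_simplified(tg, att, a0))
})

test_that("frozen-T1' approximation error is small over the bolus window", {
  err <- sensitivity_approx_error(acq0, t_step = 0.005, cbf_step = 2)
  expect_gt(err, 0.01)
  expect_lt(err, 0.02)
  # worst case is the largest perfusion, farthest from the frozen value
  err_small <- sensitivity_approx_error(acq0, cbf_max = 50, t_step = 0.005,
                                        cbf_step = 2)
  expect_lt(err_small, err)
})
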