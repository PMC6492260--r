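test_that("Fisher information is the scaled sum of sensitivity outer products", {
  # a sample before arrival carries no information
  F0 <- build_fim(0.9, cbf = 50, att = 1.0, acq0)
  expect_equal(F0$matrix, matrix(0, 2, 2), ignore_attr = TRUE)
  # linear in the number of averages; times clear of the breakpoints so
  # the finite-difference oracle is well defined
  tms <- c(1.7, 2.1, 3.0)
  F1 <- build_fim(tms, 50, 1.0, acq0, n_averages = 1)
  F2 <- build_fim(tms, 50, 1.0, acq0, n_averages = 2)
  expect_equal(F2$matrix, 2 * F1$matrix)
  # matches brute-force summation with finite-difference sensitivities
  Fb <- fim_bruteforce(tms, 50, 1.0, acq0)
  expect_equal(F1$matrix, Fb, tolerance = 1e-5, ignore_attr = TRUE)
  # symmetry and positive semi-definiteness
  expect_equal(F1$matrix[1, 2], F1$matrix[2, 1])
  expect_true(all(eigen(F1$matrix)$values >= 0))
  expect_error(build_fim(tms, 50, 1.0, acq0, noise_variance = 0),
               class = "asl_invalid_parameter")
  expect_error(build_fim(tms, 50, 1.0, acq0, n_averages = 0),
               class = "asl_invalid_parameter")
})

test_that("closed-form CRLB matches generic inversion and flags singularity", {
  expect_equal(crlb(diag(2)), diag(2), ignore_attr = TRUE)
  expect_equal(crlb(diag(c(4, 0.25))), diag(c(0.25, 4)), ignore_attr = TRUE)
  set.seed(21)
  for (i in 1:20) {
    a <- matrix(rnorm(4), 2)
    m <- crossprod(a) + 0.1 * diag(2)
    expect_equal(crlb(m), solve(m), tolerance = 1e-10, ignore_attr = TRUE)
  }
  rank1 <- c(1, 2) %o% c(1, 2)
  expect_error(crlb(rank1), class = "asl_singular_information")
})

test_that("optimality criteria reduce to the expected closed forms", {
  m <- diag(c(5, 0.2))
  expect_equal(criterion_value(m, criterion_spec("d_optimal")), 1 / (5 * 0.2))
  expect_equal(criterion_value(m, criterion_spec("l_optimal")), 1 / 5)
  wt <- criterion_spec("weighted_trace", weight_matrix = diag(2))
  expect_equal(criterion_value(m, wt), 1 / 5 + 1 / 0.2)
  expect_error(criterion_value(c(1, 2) %o% c(1, 2),
                               criterion_spec("d_optimal")),
               class = "asl_singular_information")
  expect_error(criterion_spec("weighted_trace",
                              weight_matrix = matrix(c(1, 2, 3, 4), 2)),
               class = "asl_invalid_parameter")
})

test_that("criterion values are invariant (L) or uniformly scaled (D) in CBF", {
  set.seed(33)
  # every design samples both the inflow and the decay phase at ATT 1.1
  designs <- replicate(6, sort(c(runif(2, 1.3, 2.4), runif(3, 2.6, 4))),
                       simplify = FALSE)
  for (tms in designs) {
    l_vals <- vapply(c(30, 50, 70), function(cbf) {
      criterion_value(build_fim(tms, cbf, 1.1, acq0),
                      criterion_spec("l_optimal"))
    }, numeric(1))
    expect_equal(l_vals[1], l_vals[2])
    expect_equal(l_vals[2], l_vals[3])
    d_vals <- vapply(c(30, 50, 70), function(cbf) {
      criterion_value(build_fim(tms, cbf, 1.1, acq0),
                      criterion_spec("d_optimal"))
    }, numeric(1))
    # D scales exactly as 1/f^2, so f^2 * value is constant
    expect_equal(d_vals * c(30, 50, 70)^2 / 50^2,
                 rep(d_vals[2], 3))
  }
  # argmin over designs therefore does not depend on the CBF point
  d30 <- vapply(designs, function(tms) {
    criterion_value(build_fim(tms, 30, 1.1, acq0),
                    criterion_spec("d_optimal"))
  }, numeric(1))
  d70 <- vapply(designs, function(tms) {
    criterion_value(build_fim(tms, 70, 1.1, acq0),
                    criterion_spec("d_optimal"))
  }, numeric(1))
  expect_equal(which.min(d30), which.min(d70))
})

test_that("criterion values scale with the noise variance", {
  tms <- c(1.7, 2.2, 2.9)
  for (kind in c("l_optimal", "d_optimal")) {
    v1 <- criterion_value(build_fim(tms, 50, 1.0, acq0, noise_variance = 1),
                          criterion_spec(kind))
    v3 <- criterion_value(build_fim(tms, 50, 1.0, acq0, noise_variance = 3),
                          criterion_spec(kind))
    expect_equal(v3 / v1, if (kind == "d_optimal") 9 else 3)
  }
})

test_that("single-delay mismatch bias behaves as theory dictates", {
  expect_equal(single_pld_bias(1.8, 1.0, 50, 1.0, acq0), 0,
               tolerance = 1e-6)
  # sign from the frozen-T1' linear model: the fitted CBF is the ratio of
  # true to assumed (unit-CBF) model signals
  for (case in list(c(1.25, 0.8), c(1.0, 1.6), c(1.25, 1.7))) {
    assumed <- case[1]; true_att <- case[2]
    b <- single_pld_bias(1.8, assumed, 50, true_att, acq0)
    tms <- acq0$label_duration + effective_plds(1.8, 0.053125, 5)
    num <- sum(gkm_signal(tms, 1, true_att, acq0, "fixed") *
                 gkm_signal(tms, 1, assumed, acq0, "fixed"))
    den <- sum(gkm_signal(tms, 1, assumed, acq0, "fixed")^2)
    expect_equal(sign(b), sign(50 * num / den - 50))
  }
  # high-SNR Monte Carlo mean error converges to the analytic bias
  pro <- example_protocols()$single_pld
  tiny <- noise_model(1e-7)
  mc <- run_monte_carlo(pro, att_grid = 0.8, cbf_true = 50, noise = tiny,
                        n_repeats = 50, seed = 5, acq = acq0,
                        assumed_att = 1.25)
  b_theory <- single_pld_bias(1.8, 1.25, 50, 0.8, acq0)
  expect_equal(mc$cbf_bias, b_theory, tolerance = 0.01)
  expect_error(single_pld_bias(1.8, 1.25, 50, 20, acq0),
               class = "asl_undefined_bias")
})

test_that("single-delay RMSE combines variance and bias in quadrature", {
  # matched transit time and no noise: zero error
  expect_equal(single_pld_rmse(1.8, 1.0, 50, 1.0, acq0, n_averages = 33,
                               noise_variance = 0), 0,
               tolerance = 1e-6)
  set.seed(8)
  for (i in 1:10) {
    assumed <- runif(1, 0.6, 1.7)
    true_att <- runif(1, 0.5, 1.8)
    nv <- runif(1, 1e-6, 1e-4)
    r <- single_pld_rmse(1.8, assumed, 50, true_att, acq0,
                         n_averages = 33, noise_variance = nv)
    b <- single_pld_bias(1.8, assumed, 50, true_att, acq0)
    expect_gte(r, abs(b))
    expect_gte(r + 1e-12, sqrt(r^2 - b^2))  # CRLB SD component
  }
})
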