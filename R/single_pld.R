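# Single-delay protocols: a single PLD cannot identify both CBF and ATT,
# so CBF is fitted with an assumed transit time. The theoretical error
# then combines the one-parameter CRLB variance with the systematic bias
# from the ATT mismatch.

#' Systematic CBF bias of a single-delay protocol
#'
#' The noiseless mismatch bias: the CBF value that a least-squares fit
#' with \code{assumed_att} recovers from data generated at the true
#' parameters, minus the true CBF. Zero when the assumed transit time is
#' correct.
#'
#' @param pld Post-labeling delay (s).
#' @param assumed_att Transit time assumed by the fit (s).
#' @param cbf,att True perfusion (mL/100g/min) and transit time (s).
#' @param acq An \code{\link{asl_acq}}.
#' @param n_slices,slice_duration Readout geometry; the fit uses all
#'   slices' sample times.
#' @return Bias in mL/100g/min.
#' @export
single_pld_bias <- function(pld, assumed_att, cbf, att, acq = asl_acq(),
                            n_slices = 5, slice_duration = 0.053125) {
  chk_num(pld, "pld", lower = 0.2, upper = 3.0)
  chk_num(assumed_att, "assumed_att", lower = 0)
  times <- acq$label_duration +
    effective_plds(pld, slice_duration, n_slices)
  obs <- gkm_signal(times, cbf, att, acq, t1prime_mode = "self")
  model <- gkm_signal(times, cbf, assumed_att, acq, t1prime_mode = "self")
  if (all(obs == 0) || all(model == 0)) {
    stop_undefined_bias(
      "model signal is zero at every sample time; bias is undefined")
  }
  fit <- stats::optimize(function(g) {
    sum((gkm_signal(times, g, assumed_att, acq, t1prime_mode = "self") -
           obs)^2)
  }, interval = c(0, 200), tol = 1e-10)
  fit$minimum - cbf
}

#' Theoretical RMSE of a single-delay protocol
#'
#' Combines the one-parameter Cramer-Rao variance (CBF-only information,
#' transit time treated as known at \code{assumed_att}) with the squared
#' mismatch bias: RMSE = sqrt(variance + bias^2). The information uses
#' the complete perfusion sensitivity of the self-consistent model,
#' evaluated at the mismatch solution.
#'
#' @inheritParams single_pld_bias
#' @param n_averages Number of label-control pair averages.
#' @param noise_variance Variance of one difference measurement.
#' @return RMSE in mL/100g/min.
#' @export
single_pld_rmse <- function(pld, assumed_att, cbf, att, acq = asl_acq(),
                            n_averages = 33, noise_variance = 1,
                            n_slices = 5, slice_duration = 0.053125) {
  n_averages <- chk_count(n_averages, "n_averages")
  chk_num(noise_variance, "noise_variance", lower = 0)
  bias <- single_pld_bias(pld, assumed_att, cbf, att, acq, n_slices,
                          slice_duration)
  times <- acq$label_duration +
    effective_plds(pld, slice_duration, n_slices)
  s <- cbf_sensitivity_complete(times, cbf + bias, assumed_att, acq) / 6000
  info <- n_averages * sum(s^2) / noise_variance
  if (info <= 0) {
    stop_singular("no CBF information at the assumed transit time")
  }
  sqrt(1 / info + bias^2)
}

#' Assumed transit time minimizing the mean single-delay error
#'
#' Sweeps the assumed transit time over a grid and returns the value
#' minimizing the theoretical RMSE (\code{\link{single_pld_rmse}})
#' averaged uniformly over a range of true transit times.
#'
#' @inheritParams single_pld_rmse
#' @param assumed_grid Candidate assumed transit times (s).
#' @param true_att_range Range of true transit times averaged over (s).
#' @param true_att_step Step of the true transit-time average grid (s).
#' @return The minimizing assumed transit time, with attribute
#'   \code{sweep}: data frame of candidate values and mean RMSEs.
#' @export
optimal_assumed_att <- function(pld = 1.8, cbf = 50, acq = asl_acq(),
                                n_averages = 33, noise_variance = 1,
                                assumed_grid = seq(0.5, 1.8, by = 0.05),
                                true_att_range = c(0.5, 1.8),
                                true_att_step = 0.01,
                                n_slices = 5, slice_duration = 0.053125) {
  true_grid <- seq(true_att_range[1], true_att_range[2],
                   by = true_att_step)
  mean_rmse <- vapply(assumed_grid, function(a) {
    mean(vapply(true_grid, function(at) {
      single_pld_rmse(pld, a, cbf, at, acq, n_averages, noise_variance,
                      n_slices, slice_duration)
    }, numeric(1)))
  }, numeric(1))
  best <- assumed_grid[which.min(mean_rmse)]
  structure(best,
            sweep = data.frame(assumed_att = assumed_grid,
                               mean_rmse = mean_rmse))
}
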