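# Predicted-error curves and protocol comparison reports.

#' Predicted estimation errors across transit times
#'
#' For each transit time, the Cramer-Rao lower-bound standard deviations
#' of CBF and ATT, averaged across the contributing slices (those whose
#' shortest effective delay does not exceed the transit time, matching
#' the per-slice prior truncation of the design cost). Single-delay
#' protocols have no two-parameter bound; their CBF error is the
#' theoretical RMSE combining the one-parameter bound with the
#' assumed-ATT mismatch bias (\code{\link{single_pld_rmse}}), and their
#' ATT error is \code{NA}.
#'
#' @param protocol An \code{\link{asl_protocol}}.
#' @param att_values Transit times at which to evaluate (s).
#' @param acq An \code{\link{asl_acq}}.
#' @param noise_variance Variance of one difference measurement (see
#'   \code{\link{diff_variance}}).
#' @param cbf_point Perfusion at which the ATT sensitivity is evaluated;
#'   the CBF error does not depend on it, the ATT error scales as
#'   1/CBF.
#' @param assumed_att Assumed transit time for single-delay protocols.
#' @return Data frame: \code{att}, \code{cbf_sd}, \code{att_sd},
#'   \code{n_slices_contributing}.
#' @export
predict_errors <- function(protocol, att_values = seq(0.5, 1.8, by = 0.01),
                           acq = asl_acq(), noise_variance = 1,
                           cbf_point = 50, assumed_att = 1.25) {
  stopifnot(inherits(protocol, "asl_protocol"))
  if (protocol$n_averages < 1) {
    stop_infeasible("protocol has no achievable averages")
  }
  single <- length(unique(protocol$plds)) == 1L
  if (single) {
    # theoretical RMSE per slice (each slice is fitted on its own sample,
    # as in voxelwise fitting), averaged across slices
    eff <- effective_plds(protocol$plds[1], protocol$slice_duration,
                          protocol$n_slices)
    cbf_sd <- vapply(att_values, function(a) {
      mean(vapply(eff, function(p) {
        single_pld_rmse(p, assumed_att, cbf_point, a, acq,
                        n_averages = protocol$n_averages,
                        noise_variance = noise_variance,
                        n_slices = 1, slice_duration = 0)
      }, numeric(1)))
    }, numeric(1))
    return(data.frame(att = att_values, cbf_sd = cbf_sd,
                      att_sd = NA_real_,
                      n_slices_contributing = protocol$n_slices))
  }
  scale <- noise_variance / protocol$n_averages
  rows <- vapply(att_values, function(a) {
    v_cbf <- c(); v_att <- c()
    for (k in seq_len(protocol$n_slices) - 1L) {
      min_eff <- min(protocol$plds) + k * protocol$slice_duration
      if (a <= min_eff + 1e-9) next
      times <- slice_sample_times(protocol, k)
      s1 <- cbf_sensitivity_simplified(times, a, acq) / 6000
      s2 <- att_sensitivity(times, cbf_point, a, acq,
                            t1prime_mode = "fixed")
      m11 <- sum(s1 * s1); m12 <- sum(s1 * s2); m22 <- sum(s2 * s2)
      det <- m11 * m22 - m12^2
      tr <- m11 + m22
      disc <- sqrt(max(tr^2 - 4 * det, 0))
      if (det <= 0 || (tr + disc) > COND_LIMIT * (tr - disc)) {
        v_cbf <- c(v_cbf, Inf); v_att <- c(v_att, Inf)
      } else {
        v_cbf <- c(v_cbf, sqrt(scale * m22 / det))
        v_att <- c(v_att, sqrt(scale * m11 / det))
      }
    }
    if (length(v_cbf) == 0L) c(NA_real_, NA_real_, 0) else {
      c(mean(v_cbf), mean(v_att), length(v_cbf))
    }
  }, numeric(3))
  data.frame(att = att_values, cbf_sd = rows[1, ], att_sd = rows[2, ],
             n_slices_contributing = as.integer(rows[3, ]))
}

#' Prior-averaged predicted errors of a protocol
#'
#' The mean Cramer-Rao SD of CBF and ATT over a transit-time prior, with
#' the same per-slice truncation and mass-weighted accounting as the
#' design cost: mean = sum over (ATT sample, contributing slice) of
#' SD * prior mass, divided by the total retained mass.
#'
#' @inheritParams predict_errors
#' @param prior An \code{\link{att_prior}}.
#' @return Named vector \code{c(cbf = , att = )} in (mL/100g/min, s).
#' @export
mean_crlb_sd <- function(protocol, prior, acq = asl_acq(),
                         noise_variance = 1, cbf_point = 50) {
  stopifnot(inherits(protocol, "asl_protocol"))
  if (!inherits(prior, "att_prior")) stop_invalid("prior must be att_prior")
  if (protocol$n_averages < 1) {
    stop_infeasible("protocol has no achievable averages")
  }
  scale <- noise_variance / protocol$n_averages
  num_cbf <- 0; num_att <- 0; den <- 0
  for (k in seq_len(protocol$n_slices) - 1L) {
    min_eff <- min(protocol$plds) + k * protocol$slice_duration
    sub <- truncate_below(prior, min_eff + 1e-9)
    if (attr(sub, "empty")) next
    times <- slice_sample_times(protocol, k)
    s1 <- vapply(sub$att, function(a) {
      cbf_sensitivity_simplified(times, a, acq) / 6000
    }, numeric(length(times)))
    s2 <- vapply(sub$att, function(a) {
      att_sensitivity(times, cbf_point, a, acq, t1prime_mode = "fixed")
    }, numeric(length(times)))
    s1 <- matrix(s1, nrow = length(times))
    s2 <- matrix(s2, nrow = length(times))
    m11 <- colSums(s1 * s1); m12 <- colSums(s1 * s2)
    m22 <- colSums(s2 * s2)
    det <- m11 * m22 - m12^2
    tr <- m11 + m22
    disc <- sqrt(pmax(tr^2 - 4 * det, 0))
    ok <- det > 0 & (tr + disc) <= COND_LIMIT * (tr - disc)
    num_cbf <- num_cbf + sum(sqrt(scale * m22[ok] / det[ok]) *
                               sub$weights[ok])
    num_att <- num_att + sum(sqrt(scale * m11[ok] / det[ok]) *
                               sub$weights[ok])
    den <- den + sum(sub$weights[ok])
  }
  if (den == 0) {
    stop_infeasible("no invertible (slice, ATT) pair under this prior")
  }
  c(cbf = num_cbf / den, att = num_att / den)
}

#' Compare protocols by predicted and simulated errors
#'
#' Runs \code{\link{predict_errors}} and \code{\link{run_monte_carlo}}
#' for each protocol under identical settings and seed, and summarizes
#' the mean errors across the transit-time grid.
#'
#' @param protocols Named list of \code{\link{asl_protocol}} objects
#'   (>= 2).
#' @param att_grid Transit-time grid (s).
#' @param cbf_true True perfusion for the simulations.
#' @param noise An \code{\link{noise_model}}.
#' @param n_repeats Simulated datasets per transit time.
#' @param seed Integer seed shared by all protocols.
#' @param acq An \code{\link{asl_acq}}.
#' @param assumed_att Assumed transit time for single-delay protocols.
#' @return An object of class \code{asl_comparison}: list with
#'   \code{predicted} and \code{simulated} long-format data frames (one
#'   block per protocol) and a \code{summary} data frame of grid-mean
#'   errors per protocol.
#' @export
compare_protocols <- function(protocols,
                              att_grid = seq(0.5, 1.8, by = 0.05),
                              cbf_true = 50, noise, n_repeats = 200,
                              seed, acq = asl_acq(), assumed_att = 1.25) {
  if (!is.list(protocols) || length(protocols) < 2L) {
    stop_invalid("protocols must be a list of at least two protocols")
  }
  if (is.null(names(protocols)) || any(!nzchar(names(protocols)))) {
    names(protocols) <- vapply(protocols, function(p) p$name,
                               character(1))
  }
  nv <- diff_variance(noise)
  predicted <- do.call(rbind, lapply(names(protocols), function(nm) {
    df <- predict_errors(protocols[[nm]], att_grid, acq,
                         noise_variance = nv, assumed_att = assumed_att)
    cbind(protocol = nm, df)
  }))
  simulated <- do.call(rbind, lapply(names(protocols), function(nm) {
    df <- run_monte_carlo(protocols[[nm]], att_grid, cbf_true, noise,
                          n_repeats = n_repeats, seed = seed, acq = acq,
                          assumed_att = assumed_att)
    cbind(protocol = nm, df)
  }))
  summary <- do.call(rbind, lapply(names(protocols), function(nm) {
    p <- predicted[predicted$protocol == nm, ]
    s <- simulated[simulated$protocol == nm, ]
    data.frame(protocol = nm,
               mean_pred_cbf_sd = mean(p$cbf_sd),
               mean_pred_att_sd = mean(p$att_sd),
               mean_sim_cbf_rmse = mean(s$cbf_rmse),
               mean_sim_att_rmse = mean(s$att_rmse),
               n_failed = sum(s$n_failed))
  }))
  structure(list(predicted = predicted, simulated = simulated,
                 summary = summary, seed = seed),
            class = "asl_comparison")
}

#' @export
print.asl_comparison <- function(x, ...) {
  cat("Protocol comparison (grid means)\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
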