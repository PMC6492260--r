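# Prior-averaged design cost and the coordinate-exchange search over
# post-labeling delays.
#
# The expected cost of a design is the optimality criterion averaged over
# the discretized ATT prior and over slices: each slice contributes its own
# effective sample times, with the prior truncated at the slice's shortest
# effective delay (transit times that no sample of the slice can resolve
# would make the information matrix ill-conditioned). The per-(slice, ATT)
# criterion values are weighted by the retained prior masses and normalized
# by the total retained mass, so transit times seen by more slices carry
# proportionally more weight.

# Criterion value for vectorized 2x2 entries (unit information, A and
# sigma^2 applied by the caller). Returns list(phi, bad): phi the unit
# criterion, bad flags singular/ill-conditioned entries.
crit_vec <- function(m11, m12, m22, spec) {
  det <- m11 * m22 - m12 * m12
  tr <- m11 + m22
  disc <- sqrt(pmax(tr * tr - 4 * det, 0))
  bad <- det <= 0 | (tr + disc) > COND_LIMIT * (tr - disc)
  phi <- if (spec$kind == "d_optimal") {
    1 / det
  } else {
    W <- spec$weight_matrix
    (W[1, 1] * m22 - 2 * W[1, 2] * m12 + W[2, 2] * m11) / det
  }
  phi[bad] <- 0  # flagged separately; avoid Inf/NaN propagation
  list(phi = phi, bad = bad)
}

# Scale from unit information to the criterion of F = (A/sigma^2) F_unit.
crit_scale <- function(spec, n_averages, noise_variance) {
  s <- noise_variance / n_averages
  if (spec$kind == "d_optimal") s^2 else s
}

#' Prior-averaged design cost of a protocol
#'
#' Evaluates the optimality criterion of the protocol's Fisher information
#' averaged over the ATT prior and over slices. For each slice the prior
#' is truncated below the slice's shortest effective delay
#' (\code{\link{truncate_below}}); the retained (slice, ATT) criterion
#' values are weighted by prior mass and normalized by the total retained
#' mass. A design whose retained set contains a singular information
#' matrix has infinite cost; if no (slice, ATT) pair is invertible an
#' \code{asl_infeasible_design} error is raised.
#'
#' @param protocol An \code{\link{asl_protocol}} (with
#'   \code{n_averages >= 1}).
#' @param prior An \code{\link{att_prior}}.
#' @param spec A \code{\link{criterion_spec}}.
#' @param acq An \code{\link{asl_acq}}.
#' @param cbf_point Perfusion (mL/100g/min) at which the ATT sensitivity
#'   is evaluated. The optimal design is invariant to this choice: the
#'   L-criterion does not depend on it and the D-criterion scales
#'   uniformly, so only a point value is needed.
#' @param noise_variance Variance of one difference measurement (a pure
#'   scale factor for design ranking; default 1).
#' @return Non-negative scalar cost (smaller is better), \code{Inf} for an
#'   infeasible design.
#' @export
expected_cost <- function(protocol, prior, spec = criterion_spec("d_optimal"),
                          acq = asl_acq(), cbf_point = 50,
                          noise_variance = 1) {
  stopifnot(inherits(protocol, "asl_protocol"))
  if (!inherits(prior, "att_prior")) stop_invalid("prior must be att_prior")
  if (protocol$n_averages < 1) {
    stop_infeasible("protocol has no achievable averages within its budget")
  }
  num <- 0
  den <- 0
  n_invertible <- 0L
  any_bad <- FALSE
  for (k in seq_len(protocol$n_slices) - 1L) {
    times <- slice_sample_times(protocol, k)
    min_eff <- min(protocol$plds) + k * protocol$slice_duration
    sub <- truncate_below(prior, min_eff + 1e-9)
    if (attr(sub, "empty")) next
    s1 <- vapply(sub$att, function(a) {
      cbf_sensitivity_simplified(times, a, acq) / 6000
    }, numeric(length(times)))
    s2 <- vapply(sub$att, function(a) {
      att_sensitivity(times, cbf_point, a, acq, t1prime_mode = "fixed")
    }, numeric(length(times)))
    s1 <- matrix(s1, nrow = length(times))
    s2 <- matrix(s2, nrow = length(times))
    cv <- crit_vec(colSums(s1 * s1), colSums(s1 * s2), colSums(s2 * s2),
                   spec)
    n_invertible <- n_invertible + sum(!cv$bad)
    any_bad <- any_bad || any(cv$bad)
    num <- num + sum(cv$phi[!cv$bad] * sub$weights[!cv$bad])
    den <- den + sum(sub$weights)
  }
  if (n_invertible == 0L) {
    stop_infeasible(
      "no (slice, ATT) pair yields an invertible information matrix")
  }
  if (any_bad || den == 0) return(Inf)
  crit_scale(spec, protocol$n_averages, noise_variance) * num / den
}

# Precompute per-slice sensitivity outer products on the PLD grid:
# G[[k]] holds P x r matrices g11, g12, g22 where row p is the (unit)
# information contribution of grid delay p on slice k at prior sample l.
sens_grid_tables <- function(pld_grid, prior, acq, cbf_point, n_slices,
                             slice_duration) {
  lapply(seq_len(n_slices) - 1L, function(k) {
    times <- acq$label_duration + pld_grid + k * slice_duration
    s1 <- vapply(prior$att, function(a) {
      cbf_sensitivity_simplified(times, a, acq) / 6000
    }, numeric(length(times)))
    s2 <- vapply(prior$att, function(a) {
      att_sensitivity(times, cbf_point, a, acq, t1prime_mode = "fixed")
    }, numeric(length(times)))
    list(g11 = s1 * s1, g12 = s1 * s2, g22 = s2 * s2)
  })
}

#' Optimize post-labeling delays by coordinate exchange
#'
#' Searches for the set of \code{n_plds} delays minimizing the
#' prior-averaged criterion (\code{\link{expected_cost}}) within the
#' scan-time budget. The delays live on a discrete grid
#' (\code{pld_step}); the search cyclically visits each delay and replaces
#' it with the best grid candidate between its neighbours (which keeps the
#' list sorted), recomputing the achievable number of averages for every
#' candidate set, until a full pass makes no change or \code{max_passes}
#' is reached. Ties keep the incumbent delay; candidates are scanned in
#' ascending order, so the search is deterministic.
#'
#' @param n_plds Number of delays to place (>= 2).
#' @param prior An \code{\link{att_prior}}.
#' @param spec A \code{\link{criterion_spec}} (D-optimal for joint
#'   CBF + ATT accuracy, L-optimal for CBF accuracy alone).
#' @param acq An \code{\link{asl_acq}}.
#' @param scan_time_budget Total allowed scan time (s).
#' @param n_slices,slice_duration,readout_duration Readout geometry.
#' @param pld_min,pld_max,pld_step Delay search grid (s).
#' @param init_range Delays are initialized equally spaced over this
#'   interval (snapped to the grid); ignored when \code{init} is given.
#' @param init Optional explicit initial delays.
#' @param cbf_point Perfusion point for the ATT sensitivity (the returned
#'   design is invariant to it).
#' @param max_passes Maximum number of full exchange passes.
#' @param noise_variance Pure scale factor (default 1).
#' @param verbose Print per-pass costs.
#' @return The optimized \code{\link{asl_protocol}}, with attribute
#'   \code{optimization}: list with final \code{cost}, per-pass
#'   \code{cost_trace}, \code{passes} and \code{converged}.
#' @export
optimize_plds <- function(n_plds, prior,
                          spec = criterion_spec("d_optimal"),
                          acq = asl_acq(), scan_time_budget = 300,
                          n_slices = 5, slice_duration = 0.053125,
                          readout_duration = 1.275,
                          pld_min = 0.2, pld_max = 3, pld_step = 0.025,
                          init_range = c(0.25, 1.5), init = NULL,
                          cbf_point = 50, max_passes = 50,
                          noise_variance = 1, verbose = FALSE) {
  n_plds <- chk_count(n_plds, "n_plds", min = 2L)
  if (!inherits(prior, "att_prior")) stop_invalid("prior must be att_prior")
  if (pld_min >= pld_max) stop_invalid("pld_min must be < pld_max")
  chk_num(pld_step, "pld_step", lower = 0, strict = TRUE)
  n_slices <- chk_count(n_slices, "n_slices")
  pld_grid <- seq(pld_min, pld_max, by = pld_step)
  P <- length(pld_grid)
  snap <- function(x) {
    pmin(pmax(round((x - pld_min) / pld_step), 0), P - 1) + 1L
  }
  idx <- if (is.null(init)) {
    sort(snap(seq(init_range[1], init_range[2], length.out = n_plds)))
  } else {
    if (length(init) != n_plds) stop_invalid("init has wrong length")
    sort(snap(init))
  }

  G <- sens_grid_tables(pld_grid, prior, acq, cbf_point, n_slices,
                        slice_duration)
  att <- prior$att
  w <- prior$weights
  r <- length(att)
  tau <- acq$label_duration
  fixed_cost <- n_plds * (tau + readout_duration)

  # Cost of every candidate value for one exchanged position, given the
  # summed contributions of the other delays.
  eval_candidates <- function(cand, B11, B12, B22, sum_other, min_other) {
    C <- length(cand)
    pass_cost <- 2 * (fixed_cost + sum_other + pld_grid[cand])
    A_c <- floor(scan_time_budget / pass_cost)
    min_c <- pmin(min_other, pld_grid[cand])
    num <- numeric(C)
    den <- numeric(C)
    anybad <- logical(C)
    for (k in seq_len(n_slices)) {
      m11 <- G[[k]]$g11[cand, , drop = FALSE] +
        matrix(B11[[k]], C, r, byrow = TRUE)
      m12 <- G[[k]]$g12[cand, , drop = FALSE] +
        matrix(B12[[k]], C, r, byrow = TRUE)
      m22 <- G[[k]]$g22[cand, , drop = FALSE] +
        matrix(B22[[k]], C, r, byrow = TRUE)
      cv <- crit_vec(m11, m12, m22, spec)
      thresh <- min_c + (k - 1) * slice_duration + 1e-9
      mask <- matrix(att, C, r, byrow = TRUE) > thresh
      anybad <- anybad | rowSums(cv$bad & mask) > 0
      phi <- cv$phi
      phi[!mask] <- 0
      num <- num + as.vector(phi %*% w)
      den <- den + as.vector(mask %*% w)
    }
    scale <- vapply(A_c, function(a) {
      if (a < 1) Inf else crit_scale(spec, a, noise_variance)
    }, numeric(1))
    cost <- scale * num / den
    cost[anybad | den == 0 | !is.finite(scale)] <- Inf
    cost
  }

  cost_of <- function(idx) {
    B0 <- lapply(seq_len(n_slices), function(k) numeric(r))
    one <- idx[1]
    rest <- idx[-1]
    eval_candidates(one,
                    lapply(seq_len(n_slices), function(k) {
                      colSums(G[[k]]$g11[rest, , drop = FALSE])
                    }),
                    lapply(seq_len(n_slices), function(k) {
                      colSums(G[[k]]$g12[rest, , drop = FALSE])
                    }),
                    lapply(seq_len(n_slices), function(k) {
                      colSums(G[[k]]$g22[rest, , drop = FALSE])
                    }),
                    sum(pld_grid[rest]), min(pld_grid[rest]))
  }

  cur_cost <- cost_of(idx)
  trace <- numeric(0)
  converged <- FALSE
  passes <- 0L
  for (pass in seq_len(max_passes)) {
    passes <- pass
    changed <- FALSE
    for (i in seq_len(n_plds)) {
      lo <- if (i == 1) 1L else idx[i - 1]
      hi <- if (i == n_plds) P else idx[i + 1]
      cand <- lo:hi
      rest <- idx[-i]
      B11 <- lapply(seq_len(n_slices), function(k) {
        colSums(G[[k]]$g11[rest, , drop = FALSE])
      })
      B12 <- lapply(seq_len(n_slices), function(k) {
        colSums(G[[k]]$g12[rest, , drop = FALSE])
      })
      B22 <- lapply(seq_len(n_slices), function(k) {
        colSums(G[[k]]$g22[rest, , drop = FALSE])
      })
      costs <- eval_candidates(cand, B11, B12, B22,
                               sum(pld_grid[rest]), min(pld_grid[rest]))
      inc <- which(cand == idx[i])
      best <- which.min(costs)
      if (is.finite(costs[best]) &&
          costs[best] < costs[inc] * (1 - 1e-10)) {
        idx[i] <- cand[best]
        cur_cost <- costs[best]
        changed <- TRUE
      } else {
        cur_cost <- costs[inc]
      }
    }
    trace <- c(trace, cur_cost)
    if (verbose) {
      message(sprintf("pass %d: cost %.6g", pass, cur_cost))
    }
    if (!changed) {
      converged <- TRUE
      break
    }
  }
  if (!is.finite(cur_cost)) {
    diag_msg <- paste0(
      "exchange search found no feasible design; per-slice retained prior ",
      "mass: ",
      paste(vapply(seq_len(n_slices) - 1L, function(k) {
        sub <- truncate_below(prior,
                              min(pld_grid[idx]) + k * slice_duration + 1e-9)
        sprintf("slice %d: %.3g", k, sum(sub$weights))
      }, character(1)), collapse = "; "))
    stop_optim_failed(diag_msg)
  }
  proto <- asl_protocol(pld_grid[idx], label_duration = tau,
                        readout_duration = readout_duration,
                        slice_duration = slice_duration,
                        n_slices = n_slices,
                        scan_time_budget = scan_time_budget,
                        name = sprintf("%s optimized (N=%d)", spec$kind,
                                       n_plds))
  attr(proto, "optimization") <- list(cost = cur_cost, cost_trace = trace,
                                      passes = passes,
                                      converged = converged,
                                      criterion = spec$kind)
  proto
}

#' Multi-start coordinate exchange
#'
#' The exchange search is deterministic but can stall in local optima,
#' particularly when the integer number of averages changes between
#' neighbouring designs (the feasibility boundary creates basins that a
#' one-delay-at-a-time move cannot cross). This wrapper runs
#' \code{\link{optimize_plds}} from several equally spaced initialization
#' ranges spanning the prior support and returns the lowest-cost design.
#' Starts whose initialization is infeasible for the requested number of
#' delays are skipped.
#'
#' @inheritParams optimize_plds
#' @param init_ranges List of initialization ranges \code{c(lo, hi)}.
#' @param ... Passed to \code{\link{optimize_plds}}.
#' @return The best optimized \code{\link{asl_protocol}}; attribute
#'   \code{starts} records the final cost of every start.
#' @export
optimize_plds_multi <- function(n_plds, prior,
                                spec = criterion_spec("d_optimal"),
                                init_ranges = list(c(0.25, 1.5),
                                                   c(0.2, 1.0),
                                                   c(0.4, 1.2),
                                                   c(0.5, 1.8),
                                                   c(0.2, 2.0)),
                                ...) {
  runs <- lapply(init_ranges, function(rg) {
    tryCatch(optimize_plds(n_plds, prior, spec, init_range = rg, ...),
             asl_optimization_failed = function(e) NULL)
  })
  costs <- vapply(runs, function(o) {
    if (is.null(o)) Inf else attr(o, "optimization")$cost
  }, numeric(1))
  if (all(!is.finite(costs))) {
    stop_optim_failed("every start failed to find a feasible design")
  }
  best <- runs[[which.min(costs)]]
  attr(best, "starts") <- costs
  best
}

#' Optimize over a range of delay counts
#'
#' Runs \code{\link{optimize_plds}} for each requested number of delays
#' and reports the prior-averaged cost of each design; the overall best
#' (lowest-cost) design is selected.
#'
#' @param n_values Integer vector of delay counts (each >= 2).
#' @param ... Passed to \code{\link{optimize_plds}}.
#' @return List with \code{protocols} (one per n), \code{costs} (named
#'   numeric), \code{best_n} and \code{best} (the winning protocol).
#' @export
sweep_num_plds <- function(n_values, ...) {
  if (length(n_values) == 0L) stop_invalid("n_values must be non-empty")
  protocols <- lapply(n_values, function(n) optimize_plds(n, ...))
  costs <- vapply(protocols, function(p) attr(p, "optimization")$cost,
                  numeric(1))
  names(costs) <- as.character(n_values)
  names(protocols) <- as.character(n_values)
  best <- which.min(costs)
  list(protocols = protocols, costs = costs,
       best_n = n_values[best], best = protocols[[best]])
}
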