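# Maximum-likelihood (nonlinear least squares) parameter recovery.
#
# Fitting minimizes the residual sum of squares of the self-consistent
# kinetic model within box bounds (CBF in [0, 200] mL/100g/min, ATT in
# [0, 2.5] s), started from a coarse grid search. With Gaussian noise of
# equal variance across samples this is the maximum-likelihood estimate.

DEFAULT_CBF_BOUNDS <- c(0, 200)
DEFAULT_ATT_BOUNDS <- c(0, 2.5)

#' Coarse grid-search initialization
#'
#' Exhaustively evaluates the residual sum of squares on a coarse
#' (CBF x ATT) lattice and returns the minimizing node as a starting
#' point for the bounded least-squares fit.
#'
#' @param times Sample times from the start of labeling (s).
#' @param values Observed difference signal, same length as \code{times}.
#' @param acq An \code{\link{asl_acq}}.
#' @param cbf_grid,att_grid Lattice nodes.
#' @return Named vector \code{c(cbf, att)}.
#' @export
grid_init <- function(times, values, acq = asl_acq(),
                      cbf_grid = seq(0, 200, by = 10),
                      att_grid = seq(0, 2.5, by = 0.1)) {
  chk_times(times)
  if (length(values) != length(times)) {
    stop_invalid("values must match times in length")
  }
  nodes <- expand.grid(cbf = cbf_grid, att = att_grid)
  pred <- grid_model_matrix(times, acq, cbf_grid, att_grid)
  rss <- rowSums(pred * pred) - 2 * as.vector(pred %*% values)
  i <- which.min(rss)
  c(cbf = nodes$cbf[i], att = nodes$att[i])
}

# Model predictions on the lattice: one row per (cbf, att) node. Cached by
# callers that fit many repeats of the same design.
grid_model_matrix <- function(times, acq, cbf_grid, att_grid) {
  nodes <- expand.grid(cbf = cbf_grid, att = att_grid)
  t(mapply(function(cbf, att) {
    gkm_signal(times, cbf, att, acq, t1prime_mode = "self")
  }, nodes$cbf, nodes$att))
}

#' Bounded nonlinear least-squares fit of CBF and ATT
#'
#' Levenberg-Marquardt bounded least squares on the self-consistent
#' kinetic model, with an analytic Jacobian from the package's
#' sensitivity functions. The residual noise variance is estimated as the
#' residual sum of squares divided by the statistical degrees of freedom
#' (n - 2).
#'
#' @param times Sample times (s); at least two distinct values.
#' @param values Observed difference signal.
#' @param acq An \code{\link{asl_acq}}.
#' @param start Optional starting values \code{c(cbf, att)}; defaults to
#'   \code{\link{grid_init}}.
#' @param weights Optional per-sample weights (for the per-delay
#'   variable-noise option use inverse noise SDs); default uniform.
#' @param lower,upper Box bounds on \code{c(cbf, att)}.
#' @param control A \code{minpack.lm::nls.lm.control} list.
#' @return An object of class \code{asl_fit}: list with \code{cbf_hat},
#'   \code{att_hat}, \code{residual_ss}, \code{noise_hat},
#'   \code{converged}.
#' @export
fit_nlls <- function(times, values, acq = asl_acq(), start = NULL,
                     weights = NULL,
                     lower = c(DEFAULT_CBF_BOUNDS[1], DEFAULT_ATT_BOUNDS[1]),
                     upper = c(DEFAULT_CBF_BOUNDS[2], DEFAULT_ATT_BOUNDS[2]),
                     control = minpack.lm::nls.lm.control(ftol = 1e-10,
                                                          maxiter = 200)) {
  chk_times(times)
  if (length(unique(times)) < 2L) {
    stop_invalid("at least two distinct sample times are required")
  }
  if (length(values) != length(times)) {
    stop_invalid("values must match times in length")
  }
  if (is.null(weights)) weights <- rep(1, length(times))
  if (is.null(start)) start <- grid_init(times, values, acq)
  start <- pmin(pmax(start, lower), upper)
  resid_fn <- function(p) {
    (gkm_signal(times, p[1], p[2], acq, t1prime_mode = "self") - values) *
      weights
  }
  jac_fn <- function(p) {
    cbind(cbf_sensitivity_complete(times, p[1], p[2], acq) / 6000,
          att_sensitivity(times, p[1], p[2], acq,
                          t1prime_mode = "self")) * weights
  }
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = start, fn = resid_fn, jac = jac_fn,
                         lower = lower, upper = upper, control = control)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(cbf_hat = start[1], att_hat = start[2],
                          residual_ss = sum(resid_fn(start)^2),
                          noise_hat = NA_real_, converged = FALSE),
                     class = "asl_fit"))
  }
  rss <- sum(fit$fvec^2)
  dof <- length(times) - 2L
  structure(list(cbf_hat = unname(fit$par[1]),
                 att_hat = unname(fit$par[2]),
                 residual_ss = rss,
                 noise_hat = if (dof > 0) rss / dof else NA_real_,
                 converged = fit$info %in% 1:4),
            class = "asl_fit")
}

#' One-parameter CBF fit with an assumed transit time
#'
#' For single-delay data both parameters are not identifiable, so CBF is
#' fitted with the transit time fixed at \code{assumed_att} (bounded
#' one-dimensional least squares on the self-consistent model).
#'
#' @inheritParams fit_nlls
#' @param assumed_att Transit time fixed during the fit (s).
#' @param cbf_bounds Bounds on CBF (mL/100g/min).
#' @return An \code{asl_fit}; \code{att_hat} reports \code{assumed_att}.
#' @export
fit_single_pld <- function(times, values, assumed_att, acq = asl_acq(),
                           cbf_bounds = DEFAULT_CBF_BOUNDS) {
  chk_times(times)
  if (length(values) != length(times)) {
    stop_invalid("values must match times in length")
  }
  chk_num(assumed_att, "assumed_att", lower = 0)
  sse <- function(g) {
    sum((gkm_signal(times, g, assumed_att, acq, t1prime_mode = "self") -
           values)^2)
  }
  opt <- stats::optimize(sse, interval = cbf_bounds, tol = 1e-8)
  # optimize never evaluates the interval ends; pick up a boundary optimum
  cbf_hat <- opt$minimum
  for (b in cbf_bounds) {
    if (sse(b) < opt$objective) cbf_hat <- b
  }
  rss <- sse(cbf_hat)
  dof <- length(times) - 1L
  structure(list(cbf_hat = cbf_hat, att_hat = assumed_att,
                 residual_ss = rss,
                 noise_hat = if (dof > 0) rss / dof else NA_real_,
                 converged = TRUE),
            class = "asl_fit")
}

#' @export
print.asl_fit <- function(x, ...) {
  cat(sprintf("CBF %.3f mL/100g/min, ATT %.4f s (RSS %.3g, %s)\n",
              x$cbf_hat, x$att_hat, x$residual_ss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Error metrics of a set of estimates
#'
#' Bias is the mean error, SD the sample standard deviation of the
#' estimates, and RMSE the root mean squared error. With the sample
#' (n - 1) standard deviation the identity is
#' RMSE^2 = bias^2 + SD^2 (n - 1) / n.
#'
#' @param estimates Numeric vector of estimates (>= 2).
#' @param truths True value(s); scalar or same length as
#'   \code{estimates}.
#' @return Named vector \code{c(rmse, bias, sd)}.
#' @export
error_metrics <- function(estimates, truths) {
  if (!is.numeric(estimates) || length(estimates) < 2L) {
    stop_invalid("at least two estimates are required")
  }
  err <- estimates - truths
  c(rmse = sqrt(mean(err^2)), bias = mean(err), sd = stats::sd(estimates))
}
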