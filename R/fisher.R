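# Fisher information, Cramer-Rao lower bounds, and optimality criteria
# for the two-parameter (CBF, ATT) inference problem.

# Condition number above which a 2x2 information matrix is treated as
# singular: the design search avoids such matrices by prior truncation
# rather than regularizing them.
COND_LIMIT <- 1e8

#' Fisher information matrix for a set of sample times
#'
#' Builds the 2x2 Fisher information matrix for perfusion and transit time
#' from the design sensitivities: F_jk = (A / sigma^2) * sum_i s_ij s_ik,
#' where s_i = (dSignal/dCBF, dSignal/dATT) at sample time t_i, A is the
#' number of label-control pair averages and sigma^2 the noise variance of
#' a single (unaveraged) difference measurement. The perfusion axis is in
#' mL/100g/min, so the inverse matrix gives variances directly in
#' physiological units. Sensitivities follow the design convention:
#' frozen-T1' simplified perfusion sensitivity and the analytic transit
#' time sensitivity.
#'
#' @param sample_times Times from the start of labeling (s).
#' @param cbf,att Parameter point at which sensitivities are evaluated
#'   (mL/100g/min, s).
#' @param acq An \code{\link{asl_acq}} object.
#' @param n_averages Number of label-control pair averages A (>= 1).
#' @param noise_variance Variance sigma^2 of one difference measurement.
#' @return An object of class \code{fisher_info}: list with the 2x2
#'   \code{matrix} (dimnames \code{c("cbf", "att")}), \code{n_averages}
#'   and \code{noise_variance}.
#' @examples
#' F <- build_fim(c(1.6, 2.0, 2.6), cbf = 50, att = 1.0)
#' crlb(F)
#' @export
build_fim <- function(sample_times, cbf, att, acq = asl_acq(),
                      n_averages = 1, noise_variance = 1) {
  chk_times(sample_times)
  n_averages <- chk_count(n_averages, "n_averages")
  chk_num(noise_variance, "noise_variance", lower = 0, strict = TRUE)
  s_cbf <- cbf_sensitivity_simplified(sample_times, att, acq) / 6000
  s_att <- att_sensitivity(sample_times, cbf, att, acq,
                           t1prime_mode = "fixed")
  scale <- n_averages / noise_variance
  m <- scale * rbind(c(sum(s_cbf^2), sum(s_cbf * s_att)),
                     c(sum(s_cbf * s_att), sum(s_att^2)))
  dimnames(m) <- list(c("cbf", "att"), c("cbf", "att"))
  structure(list(matrix = m, n_averages = n_averages,
                 noise_variance = noise_variance),
            class = "fisher_info")
}

as_fim_matrix <- function(F) {
  if (inherits(F, "fisher_info")) F$matrix
  else if (is.matrix(F) && all(dim(F) == c(2, 2))) F
  else stop_invalid("F must be a fisher_info object or a 2x2 matrix")
}

# Condition number of a symmetric PSD 2x2 matrix from trace and determinant.
cond_2x2 <- function(m) {
  tr <- m[1, 1] + m[2, 2]
  dt <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  disc <- sqrt(max(tr^2 - 4 * dt, 0))
  lmax <- (tr + disc) / 2
  lmin <- (tr - disc) / 2
  if (lmin <= 0) Inf else lmax / lmin
}

#' Cramer-Rao lower bound (inverse Fisher information)
#'
#' Closed-form inverse of the 2x2 information matrix. The diagonal entries
#' are the lower bounds on the CBF and ATT estimator variances. An
#' ill-conditioned matrix (condition number above 1e8, typically from a
#' lack of transit-time information when every sample time exceeds the
#' ATT) raises a \code{asl_singular_information} error.
#'
#' @param F A \code{fisher_info} object or a plain 2x2 matrix.
#' @return The 2x2 covariance lower bound.
#' @export
crlb <- function(F) {
  m <- as_fim_matrix(F)
  if (cond_2x2(m) > COND_LIMIT) {
    stop_singular(paste0(
      "Fisher information is singular or ill-conditioned ",
      "(lack of ATT information)"))
  }
  dt <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  inv <- rbind(c(m[2, 2], -m[1, 2]), c(-m[2, 1], m[1, 1])) / dt
  dimnames(inv) <- dimnames(m)
  inv
}

#' Optimality criterion specification
#'
#' \code{"d_optimal"} minimizes the determinant of the covariance bound
#' (the volume of the joint confidence ellipsoid, 1/det F);
#' \code{"l_optimal"} minimizes the CBF variance alone (the (1,1) entry of
#' the inverse information, a weighted trace with W = diag(1, 0));
#' \code{"weighted_trace"} minimizes trace(W F^-1) for an arbitrary
#' positive semi-definite weight matrix W.
#'
#' @param kind One of \code{"d_optimal"}, \code{"l_optimal"},
#'   \code{"weighted_trace"}.
#' @param weight_matrix 2x2 symmetric PSD weight matrix, required for
#'   \code{"weighted_trace"}.
#' @return An object of class \code{criterion_spec}.
#' @export
criterion_spec <- function(kind = c("d_optimal", "l_optimal",
                                    "weighted_trace"),
                           weight_matrix = NULL) {
  kind <- match.arg(kind)
  W <- switch(kind,
              d_optimal = NULL,
              l_optimal = diag(c(1, 0)),
              weighted_trace = weight_matrix)
  if (kind == "weighted_trace") {
    if (!is.matrix(W) || !all(dim(W) == c(2, 2)) ||
        !isTRUE(all.equal(W, t(W))) || any(eigen(W)$values < -1e-12)) {
      stop_invalid("weight_matrix must be a symmetric PSD 2x2 matrix")
    }
  }
  structure(list(kind = kind, weight_matrix = W), class = "criterion_spec")
}

#' Evaluate an optimality criterion on an information matrix
#'
#' @param F A \code{fisher_info} object or 2x2 matrix.
#' @param spec A \code{\link{criterion_spec}}.
#' @return Non-negative scalar criterion value (smaller is better).
#' @export
criterion_value <- function(F, spec = criterion_spec("d_optimal")) {
  if (!inherits(spec, "criterion_spec")) {
    stop_invalid("spec must be a criterion_spec object")
  }
  m <- as_fim_matrix(F)
  if (cond_2x2(m) > COND_LIMIT) {
    stop_singular("Fisher information is singular for this criterion")
  }
  dt <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (spec$kind == "d_optimal") {
    1 / dt
  } else {
    W <- spec$weight_matrix
    (W[1, 1] * m[2, 2] - 2 * W[1, 2] * m[1, 2] + W[2, 2] * m[1, 1]) / dt
  }
}
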