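# PCASL general kinetic model and analytic sensitivity functions.
#
# Internal unit convention: user-facing CBF is in mL/100g/min; the kinetic
# rate f (s^-1) is CBF/6000, so that f/lambda (lambda in mL/g) is a rate.
# Time t is measured from the start of labeling; a post-labeling delay maps
# to t = tau + PLD (+ slice offset for 2D multi-slice readouts).

#' Conversion between perfusion units and the kinetic rate
#'
#' CBF in mL/100g/min corresponds to a kinetic rate f = CBF/6000 in s^-1
#' (100 g to g, minutes to seconds), so that f/lambda with lambda in mL/g
#' is a clearance rate.
#'
#' @param cbf Perfusion in mL/100g/min.
#' @param f Kinetic rate in s^-1.
#' @return The converted value.
#' @export
cbf_to_rate <- function(cbf) cbf / 6000

#' @rdname cbf_to_rate
#' @export
rate_to_cbf <- function(f) f * 6000

#' Acquisition constants for the PCASL kinetic model
#'
#' Bundles the fixed model parameters: label duration tau, labeling
#' efficiency alpha, brain--blood partition coefficient lambda, the
#' longitudinal relaxation times of arterial blood and tissue, the
#' equilibrium blood magnetization, and the perfusion value at which the
#' apparent tissue relaxation time T1' is frozen inside the design
#' calculations. Defaults are representative 3T values for gray matter.
#'
#' @param label_duration Labeling duration tau (s).
#' @param labeling_efficiency Labeling efficiency alpha, in (0, 1].
#' @param partition_coeff Brain--blood water partition coefficient lambda
#'   (mL/g).
#' @param t1_blood Longitudinal relaxation time of arterial blood (s).
#' @param t1_tissue Longitudinal relaxation time of tissue (s).
#' @param m0_blood Equilibrium magnetization of arterial blood (signal
#'   units); the difference signal is linear in this scale factor.
#' @param fixed_outflow_cbf Perfusion (mL/100g/min) used to freeze T1' in
#'   the simplified sensitivity functions.
#' @return An object of class \code{asl_acq}.
#' @examples
#' acq <- asl_acq()
#' acq$label_duration
#' @export
asl_acq <- function(label_duration = 1.4,
                    labeling_efficiency = 0.85,
                    partition_coeff = 0.9,
                    t1_blood = 1.65,
                    t1_tissue = 1.445,
                    m0_blood = 1,
                    fixed_outflow_cbf = 50) {
  chk_num(label_duration, "label_duration", lower = 0, strict = TRUE)
  chk_num(labeling_efficiency, "labeling_efficiency", lower = 0,
          upper = 1, strict = TRUE, upper_closed = TRUE)
  chk_num(partition_coeff, "partition_coeff", lower = 0, strict = TRUE)
  chk_num(t1_blood, "t1_blood", lower = 0, strict = TRUE)
  chk_num(t1_tissue, "t1_tissue", lower = 0, strict = TRUE)
  chk_num(m0_blood, "m0_blood", lower = 0, strict = TRUE)
  chk_num(fixed_outflow_cbf, "fixed_outflow_cbf", lower = 0)
  structure(list(label_duration = label_duration,
                 labeling_efficiency = labeling_efficiency,
                 partition_coeff = partition_coeff,
                 t1_blood = t1_blood,
                 t1_tissue = t1_tissue,
                 m0_blood = m0_blood,
                 fixed_outflow_cbf = fixed_outflow_cbf),
            class = "asl_acq")
}

#' @export
print.asl_acq <- function(x, ...) {
  cat("PCASL acquisition constants\n")
  cat(sprintf("  label duration (tau): %.4g s\n", x$label_duration))
  cat(sprintf("  labeling efficiency (alpha): %.4g\n", x$labeling_efficiency))
  cat(sprintf("  partition coefficient (lambda): %.4g mL/g\n",
              x$partition_coeff))
  cat(sprintf("  T1 blood: %.4g s, T1 tissue: %.4g s\n",
              x$t1_blood, x$t1_tissue))
  cat(sprintf("  M0 blood: %.4g, fixed outflow CBF for T1': %.4g mL/100g/min\n",
              x$m0_blood, x$fixed_outflow_cbf))
  invisible(x)
}

#' Apparent tissue relaxation time
#'
#' The outflow-corrected tissue relaxation time 1/T1' = 1/T1t + f/lambda.
#' Monotonically decreasing in f and equal to T1t at zero flow.
#'
#' @param f Kinetic rate in s^-1 (use \code{cbf_to_rate} for perfusion
#'   units); may be a vector.
#' @param acq An \code{\link{asl_acq}} object.
#' @return Apparent T1' in seconds.
#' @export
apparent_t1 <- function(f, acq = asl_acq()) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0)) {
    stop_invalid("f must be finite and non-negative")
  }
  1 / (1 / acq$t1_tissue + f / acq$partition_coeff)
}

# T1' used by a given mode: the sample's own f ("self") or the frozen
# outflow value ("fixed", used throughout the design calculations).
t1prime_for <- function(f, acq, t1prime_mode) {
  switch(t1prime_mode,
         self = apparent_t1(f, acq),
         fixed = apparent_t1(cbf_to_rate(acq$fixed_outflow_cbf), acq),
         stop_invalid("t1prime_mode must be 'self' or 'fixed'"))
}

# Piecewise kinetic curve in rate units, vectorized over t. Breakpoint
# ownership: t = att starts the inflow branch, t = tau + att the decay
# branch (the curve is continuous at both, so this is inconsequential).
gkm_core <- function(t, f, att, t1p, acq) {
  tau <- acq$label_duration
  amp <- 2 * acq$m0_blood * f * t1p * acq$labeling_efficiency *
    exp(-att / acq$t1_blood)
  out <- numeric(length(t))
  inflow <- t >= att & t < tau + att
  decay <- t >= tau + att
  out[inflow] <- amp * (1 - exp(-(t[inflow] - att) / t1p))
  out[decay] <- amp * exp(-(t[decay] - tau - att) / t1p) *
    (1 - exp(-tau / t1p))
  out
}

#' PCASL label-control difference signal (general kinetic model)
#'
#' Evaluates the piecewise general kinetic model for the difference signal:
#' zero before the label arrives (t < ATT), an inflow phase while the bolus
#' is arriving (ATT <= t < tau + ATT), and T1'-weighted decay afterwards.
#' The curve is continuous at both breakpoints and peaks at t = tau + ATT.
#'
#' @param t Time from the start of labeling (s); may be a vector.
#' @param cbf Perfusion in mL/100g/min.
#' @param att Arterial transit time (s).
#' @param acq An \code{\link{asl_acq}} object.
#' @param t1prime_mode How the apparent T1' is evaluated: \code{"self"}
#'   uses the sample's own perfusion (used for simulation and fitting);
#'   \code{"fixed"} freezes it at \code{acq$fixed_outflow_cbf} (used inside
#'   the design calculations, where it makes the signal exactly linear in
#'   perfusion).
#' @return Difference signal in the units of \code{acq$m0_blood}.
#' @examples
#' acq <- asl_acq()
#' gkm_signal(1.9, cbf = 50, att = 0.5, acq)  # bolus peak
#' @export
gkm_signal <- function(t, cbf, att, acq = asl_acq(),
                       t1prime_mode = c("self", "fixed")) {
  t1prime_mode <- match.arg(t1prime_mode)
  chk_times(t)
  chk_num(cbf, "cbf", lower = 0)
  chk_num(att, "att", lower = 0)
  f <- cbf_to_rate(cbf)
  gkm_core(t, f, att, t1prime_for(f, acq, t1prime_mode), acq)
}

#' Sensitivity of the difference signal to perfusion
#'
#' \code{cbf_sensitivity_simplified} is the kinetic curve per unit rate with
#' T1' frozen at \code{acq$fixed_outflow_cbf}: because the frozen-T1' model
#' is exactly linear in f, the derivative is the signal divided by f and is
#' independent of the perfusion at which it is evaluated.
#' \code{cbf_sensitivity_complete} is the full derivative of the
#' self-consistent model, including the dependence of T1' on f through the
#' outflow term (chain rule with dT1'/df = -T1'^2/lambda).
#'
#' Both return the derivative with respect to the rate f (signal units per
#' s^-1); divide by 6000 for the derivative with respect to perfusion in
#' mL/100g/min.
#'
#' @inheritParams gkm_signal
#' @return Sensitivity values, one per element of \code{t}.
#' @export
cbf_sensitivity_simplified <- function(t, att, acq = asl_acq()) {
  chk_times(t)
  chk_num(att, "att", lower = 0)
  t1p <- apparent_t1(cbf_to_rate(acq$fixed_outflow_cbf), acq)
  gkm_core(t, 1, att, t1p, acq)
}

#' @rdname cbf_sensitivity_simplified
#' @export
cbf_sensitivity_complete <- function(t, cbf, att, acq = asl_acq()) {
  chk_times(t)
  chk_num(cbf, "cbf", lower = 0)
  chk_num(att, "att", lower = 0)
  f <- cbf_to_rate(cbf)
  t1p <- apparent_t1(f, acq)
  tau <- acq$label_duration
  # partial derivative at fixed T1' (model is linear in f at fixed T1')
  fixed_part <- gkm_core(t, 1, att, t1p, acq)
  # partial derivative with respect to T1', branch by branch
  amp0 <- 2 * acq$m0_blood * f * acq$labeling_efficiency *
    exp(-att / acq$t1_blood)
  dT1p <- numeric(length(t))
  inflow <- t >= att & t < tau + att
  decay <- t >= tau + att
  u <- t[inflow] - att
  E <- exp(-u / t1p)
  dT1p[inflow] <- amp0 * ((1 - E) - E * u / t1p)
  v <- t[decay] - tau - att
  D <- exp(-v / t1p)
  K <- exp(-tau / t1p)
  dT1p[decay] <- amp0 * (D * (1 - K) + D * v * (1 - K) / t1p -
                           D * K * tau / t1p)
  fixed_part + dT1p * (-t1p^2 / acq$partition_coeff)
}

#' Sensitivity of the difference signal to the arterial transit time
#'
#' Analytic derivative of the kinetic curve with respect to ATT, zero
#' before arrival and proportional to perfusion. By default T1' is frozen
#' at \code{acq$fixed_outflow_cbf} (the design convention); with
#' \code{t1prime_mode = "self"} it matches the self-consistent model.
#'
#' @inheritParams gkm_signal
#' @return Sensitivity in signal units per second.
#' @export
att_sensitivity <- function(t, cbf, att, acq = asl_acq(),
                            t1prime_mode = c("fixed", "self")) {
  t1prime_mode <- match.arg(t1prime_mode)
  chk_times(t)
  chk_num(cbf, "cbf", lower = 0)
  chk_num(att, "att", lower = 0)
  f <- cbf_to_rate(cbf)
  t1p <- t1prime_for(f, acq, t1prime_mode)
  tau <- acq$label_duration
  amp <- 2 * acq$m0_blood * f * t1p * acq$labeling_efficiency *
    exp(-att / acq$t1_blood)
  out <- numeric(length(t))
  inflow <- t >= att & t < tau + att
  decay <- t >= tau + att
  E <- exp(-(t[inflow] - att) / t1p)
  out[inflow] <- amp * (-1 / acq$t1_blood -
                          E * (1 / t1p - 1 / acq$t1_blood))
  out[decay] <- amp * exp(-(t[decay] - tau - att) / t1p) *
    (1 - exp(-tau / t1p)) * (1 / t1p - 1 / acq$t1_blood)
  out
}

#' Accuracy of the frozen-T1' perfusion sensitivity
#'
#' Maximum relative deviation of the simplified (frozen-T1') perfusion
#' sensitivity from the complete derivative of the self-consistent model,
#' over a grid of true perfusion values and a dense time grid spanning the
#' bolus window (arrival to bolus peak, where the inflowing label carries
#' the perfusion information). Beyond the peak the two models decay with
#' different rates, so the pointwise deviation grows without bound and a
#' bounded comparison window is required; see the package vignette.
#'
#' @param acq An \code{\link{asl_acq}} object.
#' @param cbf_max Largest true perfusion evaluated (mL/100g/min).
#' @param att Transit time at which the curves are compared (the relative
#'   deviation is independent of this choice).
#' @param cbf_step,t_step Grid resolutions for perfusion and time.
#' @return Maximum relative deviation (fraction, not percent), with
#'   attribute \code{n_grid} giving the number of (f, t) points evaluated.
#' @export
sensitivity_approx_error <- function(acq = asl_acq(), cbf_max = 100,
                                     att = 0.5, cbf_step = 0.5,
                                     t_step = 0.001) {
  tg <- seq(att + t_step, att + acq$label_duration, by = t_step)
  simp <- cbf_sensitivity_simplified(tg, att, acq)
  cbf_grid <- seq(0, cbf_max, by = cbf_step)
  worst <- 0
  for (cbf in cbf_grid) {
    comp <- cbf_sensitivity_complete(tg, cbf, att, acq)
    worst <- max(worst, max(abs(simp - comp) / abs(comp)))
  }
  structure(worst, n_grid = length(tg) * length(cbf_grid))
}
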