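# Discretized transit-time prior: uniform over a core range with linear
# tapers, used to average the optimality criterion across plausible ATTs.

#' Tapered-uniform arterial transit time prior
#'
#' Builds a discretized prior over ATT: constant weight on the core range,
#' extended on either side by a taper over which the weight decreases
#' linearly to exactly zero at the support edges. Weights are normalized
#' to sum to one. The taper avoids hard edge effects in the prior-averaged
#' design; the default core range covers gray matter in healthy adults.
#'
#' @param core_min,core_max Core (plateau) range of transit times (s).
#' @param taper Width of the linear taper added on each side (s).
#' @param step Discretization step (s); samples are equally spaced across
#'   the full support \code{[core_min - taper, core_max + taper]}.
#' @return An object of class \code{att_prior}: list with \code{att}
#'   (sample locations), \code{weights}, \code{core_range}, \code{taper},
#'   \code{step}.
#' @examples
#' p <- att_prior()          # 0.5-1.8 s core, 0.3 s taper
#' range(p$att)              # support 0.2-2.1 s
#' sum(p$weights)
#' @export
att_prior <- function(core_min = 0.5, core_max = 1.8, taper = 0.3,
                      step = 0.001) {
  chk_num(core_min, "core_min", lower = 0)
  chk_num(core_max, "core_max")
  if (core_min >= core_max) stop_invalid("core_min must be < core_max")
  chk_num(taper, "taper", lower = 0)
  chk_num(step, "step", lower = 0, strict = TRUE)
  lo <- core_min - taper
  hi <- core_max + taper
  if (step > hi - lo) stop_invalid("step is larger than the prior support")
  att <- seq(lo, hi, by = step)
  w <- rep(1, length(att))
  if (taper > 0) {
    left <- att < core_min
    right <- att > core_max
    w[left] <- (att[left] - lo) / taper
    w[right] <- (hi - att[right]) / taper
  }
  w <- w / sum(w)
  structure(list(att = att, weights = w,
                 core_range = c(core_min, core_max),
                 taper = taper, step = step),
            class = "att_prior")
}

#' Transit-time prior with arbitrary weights
#'
#' Constructor for a discretized prior from explicit sample locations and
#' non-negative weights (normalized to sum to one).
#'
#' @param att Strictly increasing sample locations (s).
#' @param weights Non-negative weights, same length as \code{att}.
#' @return An \code{att_prior} object.
#' @export
att_prior_weights <- function(att, weights) {
  if (!is.numeric(att) || length(att) == 0L || any(diff(att) <= 0)) {
    stop_invalid("att must be strictly increasing")
  }
  if (length(weights) != length(att) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop_invalid("weights must be non-negative and not all zero")
  }
  structure(list(att = att, weights = weights / sum(weights),
                 core_range = range(att), taper = 0,
                 step = if (length(att) > 1) min(diff(att)) else NA_real_),
            class = "att_prior")
}

#' Truncate a prior from below
#'
#' Restricts the prior to transit times at or above \code{min_att}. The
#' retained weights are deliberately NOT renormalized: in multi-slice
#' designs each slice truncates the shared prior at its own shortest
#' effective delay, and keeping the original masses makes the cross-slice
#' weighting consistent. An empty result is valid and signals that the
#' slice contributes no information at any prior transit time.
#'
#' @param prior An \code{att_prior}.
#' @param min_att Smallest transit time to retain (s).
#' @return An \code{att_prior} (possibly empty, flagged by
#'   \code{attr(, "empty")}); weights keep their original masses.
#' @export
truncate_below <- function(prior, min_att) {
  if (!inherits(prior, "att_prior")) stop_invalid("prior must be att_prior")
  chk_num(min_att, "min_att")
  keep <- prior$att >= min_att - 1e-12
  out <- prior
  out$att <- prior$att[keep]
  out$weights <- prior$weights[keep]
  attr(out, "empty") <- length(out$att) == 0L
  out
}

#' @export
print.att_prior <- function(x, ...) {
  if (length(x$att) == 0L) {
    cat("ATT prior: empty (fully truncated)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "ATT prior: %d samples on [%.3g, %.3g] s (core [%.3g, %.3g], taper %.3g)\n",
    length(x$att), min(x$att), max(x$att),
    x$core_range[1], x$core_range[2], x$taper))
  cat(sprintf("  total mass %.6g\n", sum(x$weights)))
  invisible(x)
}
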