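# Input validation and classed error conditions.

stop_invalid <- function(msg) {
  stop(structure(class = c("asl_invalid_parameter", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_singular <- function(msg) {
  stop(structure(class = c("asl_singular_information", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_infeasible <- function(msg) {
  stop(structure(class = c("asl_infeasible_design", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_optim_failed <- function(msg) {
  stop(structure(class = c("asl_optimization_failed", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_undefined_bias <- function(msg) {
  stop(structure(class = c("asl_undefined_bias", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

chk_num <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE,
                    upper_closed = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("%s must be a single finite number", name))
  }
  lo_ok <- if (strict) x > lower else x >= lower
  hi_ok <- if (upper_closed) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    stop_invalid(sprintf("%s = %g is outside its valid range", name, x))
  }
  invisible(x)
}

chk_times <- function(t) {
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t)) || any(t < 0)) {
    stop_invalid("t must be a non-empty vector of finite, non-negative times")
  }
  invisible(t)
}

chk_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop_invalid(sprintf("%s must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}
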