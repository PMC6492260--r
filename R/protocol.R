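# Protocols: an ordered set of post-labeling delays plus readout geometry
# and the number of averages achievable in the scan-time budget.

#' Number of label-control pair averages within a scan-time budget
#'
#' One acquisition of a delay costs (label duration + PLD + readout) for
#' the label image and the same again for the control image, so a full
#' pass over the delay list costs 2 * sum(tau + PLD + readout) seconds
#' (variable TR: short delays are acquired with correspondingly short
#' repetition times). The achievable number of averages is the floor of
#' the budget divided by this pass cost; zero signals an infeasible
#' design.
#'
#' @param plds Post-labeling delays (s).
#' @param label_duration Label duration tau (s).
#' @param readout_duration Readout duration (s).
#' @param scan_time_budget Total allowed scan time (s).
#' @return Integer number of averages (possibly 0).
#' @examples
#' compute_averages(c(0.25, 0.5, 0.75, 1, 1.25, 1.5), 1.4, 1.275, 300)  # 7
#' compute_averages(1.8, 1.4, 1.275, 300)                               # 33
#' @export
compute_averages <- function(plds, label_duration, readout_duration,
                             scan_time_budget) {
  if (length(plds) == 0L) stop_invalid("plds must be non-empty")
  chk_num(scan_time_budget, "scan_time_budget", lower = 0, strict = TRUE)
  pass_cost <- 2 * sum(label_duration + plds + readout_duration)
  as.integer(floor(scan_time_budget / pass_cost))
}

#' Per-slice effective post-labeling delays
#'
#' In a 2D multi-slice readout, slice k (0-based) is acquired
#' k * slice_duration after the first, so its effective delay is
#' \code{pld + k * slice_duration}. The model sample time of slice k is
#' \code{label_duration + effective PLD}.
#'
#' @param pld Nominal post-labeling delay (s).
#' @param slice_duration Acquisition time of one slice (s).
#' @param n_slices Number of slices (>= 1).
#' @return Vector of \code{n_slices} effective delays, strictly increasing
#'   when \code{slice_duration > 0}.
#' @export
effective_plds <- function(pld, slice_duration, n_slices) {
  chk_num(pld, "pld", lower = 0)
  chk_num(slice_duration, "slice_duration", lower = 0)
  n_slices <- chk_count(n_slices, "n_slices")
  pld + (seq_len(n_slices) - 1) * slice_duration
}

#' ASL protocol
#'
#' A protocol is the design variable: an ordered list of post-labeling
#' delays plus the readout geometry, scan-time budget and number of
#' averages. When \code{n_averages} is omitted it is computed from the
#' budget with \code{\link{compute_averages}}.
#'
#' @param plds Post-labeling delays (s); sorted non-decreasing.
#' @param label_duration,readout_duration,slice_duration Timing constants
#'   (s).
#' @param n_slices Number of 2D slices (1 for 3D/single-slice readouts).
#' @param scan_time_budget Total allowed scan time (s).
#' @param n_averages Number of label-control pair averages; computed from
#'   the budget when \code{NULL}.
#' @param name Optional protocol name.
#' @return An object of class \code{asl_protocol}.
#' @export
asl_protocol <- function(plds, label_duration = 1.4,
                         readout_duration = 1.275,
                         slice_duration = 0.053125, n_slices = 5,
                         scan_time_budget = 300, n_averages = NULL,
                         name = "") {
  if (!is.numeric(plds) || length(plds) == 0L || any(!is.finite(plds)) ||
      any(plds < 0)) {
    stop_invalid("plds must be non-negative finite numbers")
  }
  plds <- sort(plds)
  chk_num(label_duration, "label_duration", lower = 0, strict = TRUE)
  chk_num(readout_duration, "readout_duration", lower = 0)
  chk_num(slice_duration, "slice_duration", lower = 0)
  n_slices <- chk_count(n_slices, "n_slices")
  auto_a <- compute_averages(plds, label_duration, readout_duration,
                             scan_time_budget)
  if (is.null(n_averages)) {
    n_averages <- auto_a
  } else {
    n_averages <- chk_count(n_averages, "n_averages", min = 0L)
  }
  structure(list(plds = plds, label_duration = label_duration,
                 readout_duration = readout_duration,
                 slice_duration = slice_duration, n_slices = n_slices,
                 n_averages = n_averages,
                 scan_time_budget = scan_time_budget, name = name),
            class = "asl_protocol")
}

#' Total scan time of a protocol
#'
#' @param protocol An \code{asl_protocol}.
#' @return Scan time in seconds:
#'   \code{2 * n_averages * sum(tau + PLD + readout)}.
#' @export
scan_time <- function(protocol) {
  stopifnot(inherits(protocol, "asl_protocol"))
  2 * protocol$n_averages *
    sum(protocol$label_duration + protocol$plds + protocol$readout_duration)
}

# Sample times (from the start of labeling) of one slice.
slice_sample_times <- function(protocol, slice) {
  protocol$label_duration +
    effective_plds_vec(protocol$plds, protocol$slice_duration, slice)
}

# effective_plds for a vector of plds and a single 0-based slice index
effective_plds_vec <- function(plds, slice_duration, slice) {
  plds + slice * slice_duration
}

#' @export
print.asl_protocol <- function(x, ...) {
  cat(sprintf("ASL protocol%s\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else ""))
  cat(sprintf("  %d PLDs (s): %s\n", length(x$plds),
              paste(format(x$plds, trim = TRUE), collapse = ", ")))
  cat(sprintf(
    "  tau %.4g s, readout %.4g s, %d slices x %.4g ms, %d average(s)\n",
    x$label_duration, x$readout_duration, x$n_slices,
    1000 * x$slice_duration, x$n_averages))
  cat(sprintf("  scan time %.4g s (budget %.4g s)\n", scan_time(x),
              x$scan_time_budget))
  invisible(x)
}

#' Read and write protocol files
#'
#' Protocols are stored as JSON with keys \code{name}, \code{plds_s},
#' \code{label_duration_s}, \code{readout_duration_s},
#' \code{slice_duration_s}, \code{n_slices}, \code{n_averages},
#' \code{scan_time_budget_s}. A CSV alternative with one \code{pld_s} per
#' row (protocol-level fields as leading comment lines \code{# key: value})
#' is read by extension.
#'
#' @param path File path (\code{.json} or \code{.csv}).
#' @param protocol An \code{asl_protocol} to write.
#' @return \code{read_protocol} returns an \code{asl_protocol};
#'   \code{write_protocol} returns \code{path} invisibly.
#' @export
read_protocol <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    return(read_protocol_csv(path))
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  asl_protocol(plds = x$plds_s,
               label_duration = x$label_duration_s,
               readout_duration = x$readout_duration_s,
               slice_duration = x$slice_duration_s,
               n_slices = x$n_slices,
               scan_time_budget = x$scan_time_budget_s,
               n_averages = x$n_averages,
               name = if (is.null(x$name)) "" else x$name)
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "asl_protocol"))
  jsonlite::write_json(
    list(name = protocol$name,
         plds_s = protocol$plds,
         label_duration_s = protocol$label_duration,
         readout_duration_s = protocol$readout_duration,
         slice_duration_s = protocol$slice_duration,
         n_slices = protocol$n_slices,
         n_averages = protocol$n_averages,
         scan_time_budget_s = protocol$scan_time_budget),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_protocol_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!"pld_s" %in% names(body)) stop_invalid("CSV must have a pld_s column")
  num <- function(key, default) {
    if (!is.null(meta[[key]])) as.numeric(meta[[key]]) else default
  }
  asl_protocol(plds = body$pld_s,
               label_duration = num("label_duration_s", 1.4),
               readout_duration = num("readout_duration_s", 1.275),
               slice_duration = num("slice_duration_s", 0.053125),
               n_slices = as.integer(num("n_slices", 5)),
               scan_time_budget = num("scan_time_budget_s", 300),
               name = if (!is.null(meta$name)) meta$name else "")
}

#' Built-in example protocols
#'
#' Loads the four bundled 5-slice protocols used throughout the package
#' examples and tests: a single-delay protocol (PLD 1.8 s, 33 averages),
#' an evenly spaced reference multi-delay protocol (0.25-1.5 s, 7
#' averages), and two CRLB-optimized designs (a 40-delay design optimized
#' for joint CBF and ATT accuracy and a 34-delay design optimized for CBF
#' accuracy alone), all within a 5-minute budget.
#'
#' @return Named list of \code{asl_protocol} objects:
#'   \code{single_pld}, \code{reference_multi_pld}, \code{cbf_att_opt},
#'   \code{cbf_opt}.
#' @export
example_protocols <- function() {
  dir <- system.file("extdata", package = "asldesign")
  files <- c(single_pld = "protocol-single-pld.json",
             reference_multi_pld = "protocol-reference-multi-pld.json",
             cbf_att_opt = "protocol-cbf-att-opt.json",
             cbf_opt = "protocol-cbf-opt.json")
  lapply(files, function(f) read_protocol(file.path(dir, f)))
}
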