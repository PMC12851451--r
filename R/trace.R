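#' Construct a single voltage-clamp sweep
#'
#' A `sweep_trace` holds one repetition of the stimulation protocol: the
#' recorded membrane current, the command voltage, and the (uniform) time
#' grid. Time of sample `n` is `n * ts` seconds, counting from 0.
#'
#' @param current Numeric vector, membrane current in pA.
#' @param voltage_cmd Numeric vector, command voltage in mV; same length as
#'   `current`.
#' @param ts Sampling period in seconds. Exactly one of `ts` and `time` must
#'   be supplied.
#' @param time Optional explicit time vector in seconds; must be a strictly
#'   increasing uniform grid (relative step tolerance 1e-9), from which `ts`
#'   is inferred.
#'
#' @return An object of class `sweep_trace`: a list with elements `time`
#'   (seconds), `current` (pA), `voltage_cmd` (mV) and `ts` (seconds).
#' @export
sweep_trace <- function(current, voltage_cmd, ts = NULL, time = NULL) {
  current <- as.numeric(current)
  voltage_cmd <- as.numeric(voltage_cmd)
  n <- length(current)
  if (n < 2L) {
    stop("a sweep needs at least 2 samples", call. = FALSE)
  }
  if (length(voltage_cmd) != n) {
    stop("`current` and `voltage_cmd` must have identical length", call. = FALSE)
  }
  if (is.null(ts) == is.null(time)) {
    stop("supply exactly one of `ts` or `time`", call. = FALSE)
  }
  if (is.null(ts)) {
    time <- as.numeric(time)
    if (length(time) != n) {
      stop("`time` must match the length of `current`", call. = FALSE)
    }
    dt <- diff(time)
    if (any(dt <= 0)) {
      stop("`time` must be strictly increasing", call. = FALSE)
    }
    ts <- dt[1L]
    if (any(abs(dt - ts) > 1e-9 * max(abs(ts), 1e-300))) {
      stop("`time` must be a uniform grid (constant step)", call. = FALSE)
    }
  } else {
    if (!is.numeric(ts) || length(ts) != 1L || ts <= 0) {
      stop("`ts` must be a single positive number", call. = FALSE)
    }
    time <- (seq_len(n) - 1L) * ts
  }
  structure(
    list(time = time, current = current, voltage_cmd = voltage_cmd, ts = ts),
    class = "sweep_trace"
  )
}

#' @export
print.sweep_trace <- function(x, ...) {
  cat(sprintf(
    "<sweep_trace> %d samples, Ts = %g ms (%.1f ms), current [%.1f, %.1f] pA\n",
    length(x$current), x$ts * 1e3, length(x$current) * x$ts * 1e3,
    min(x$current), max(x$current)
  ))
  invisible(x)
}

#' @export
length.sweep_trace <- function(x) length(x$current)

#' Construct a cell recording (train of sweeps)
#'
#' Bundles the ordered sweeps recorded from one cell under the repeated
#' stimulation protocol, together with the cell identity, the (possibly
#' unknown) beat-to-beat regime label and the stimulation frequency. All
#' sweeps must share the same sampling period and length, and at least two
#' sweeps are required because alternans is defined on consecutive sweep
#' pairs (the canonical protocol has 30).
#'
#' @param sweeps List of [sweep_trace()] objects.
#' @param cell_id Character scalar naming the cell.
#' @param regime_label One of `"uniform"`, `"alternant"`, `"unknown"`.
#' @param stimulation_frequency Stimulation frequency in Hz (`NA` if unknown).
#'
#' @return An object of class `cell_recording`.
#' @export
cell_recording <- function(sweeps, cell_id = "cell",
                           regime_label = c("unknown", "uniform", "alternant"),
                           stimulation_frequency = NA_real_) {
  regime_label <- match.arg(regime_label)
  if (!is.list(sweeps) || !all(vapply(sweeps, inherits, logical(1), "sweep_trace"))) {
    stop("`sweeps` must be a list of sweep_trace objects", call. = FALSE)
  }
  if (length(sweeps) < 2L) {
    stop("a recording needs at least 2 sweeps (alternans is pairwise)", call. = FALSE)
  }
  ts <- vapply(sweeps, function(s) s$ts, numeric(1))
  len <- vapply(sweeps, length, integer(1))
  if (any(abs(ts - ts[1L]) > 1e-12 * ts[1L]) || any(len != len[1L])) {
    stop("all sweeps must share the same sampling period and length", call. = FALSE)
  }
  structure(
    list(
      cell_id = as.character(cell_id)[1L],
      sweeps = sweeps,
      regime_label = regime_label,
      stimulation_frequency = stimulation_frequency
    ),
    class = "cell_recording"
  )
}

#' @export
print.cell_recording <- function(x, ...) {
  cat(sprintf(
    "<cell_recording> '%s': %d sweeps x %d samples (Ts = %g ms), regime = %s\n",
    x$cell_id, length(x$sweeps), length(x$sweeps[[1L]]),
    x$sweeps[[1L]]$ts * 1e3, x$regime_label
  ))
  invisible(x)
}

#' Number of sweeps in a recording
#' @param rec A [cell_recording()].
#' @return Integer sweep count.
#' @export
n_sweeps <- function(rec) {
  stopifnot(inherits(rec, "cell_recording"))
  length(rec$sweeps)
}
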