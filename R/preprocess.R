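# Preprocessing: moving-average smoothing calibrated by an energy
# heuristic, and snapping of the recorded command voltage onto the
# theoretical stimulation levels.

#' Smoothing filter specification
#'
#' @param k Target energy-attenuation fraction for the window-length
#'   heuristic (dimensionless, default 0.02, i.e. attenuate 2% of the
#'   signal energy).
#' @param L Fixed window length in samples; when `NULL` (default) the
#'   length is chosen per trace by [window_length_from_energy()].
#' @param L_max Search cap for the heuristic (default 50 samples).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(k = 0.02, L = NULL, L_max = 50L) {
  stopifnot(k >= 0, k < 1, L_max >= 1)
  if (!is.null(L)) stopifnot(L >= 1, L <= L_max)
  structure(list(k = k, L = L, L_max = as.integer(L_max)), class = "filter_spec")
}

#' Causal moving-average filter
#'
#' Convolves the signal with a rectangular window of length `L`. The edge
#' is handled by causal truncation: output sample `n` is the mean of
#' samples `max(1, n - L + 1) .. n`, so the output has the input's length
#' and no future sample leaks backwards (which matters ahead of the sharp
#' capacitive transients). `L = 1` returns the input unchanged.
#'
#' @param current Numeric sample series (pA).
#' @param L Window length in samples (`>= 1`, `<=` series length).
#' @return Filtered series, same length.
#' @export
moving_average_filter <- function(current, L) {
  n <- length(current)
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  if (L > n) stop("window length L exceeds the series length", call. = FALSE)
  if (L == 1L) return(current)
  cs <- cumsum(current)
  out <- numeric(n)
  head_idx <- seq_len(L - 1L)
  out[head_idx] <- cs[head_idx] / head_idx
  idx <- L:n
  out[idx] <- (cs[idx] - c(0, cs)[idx - L + 1L]) / L
  out
}

#' Heuristic window length from target energy attenuation
#'
#' Returns the smallest window length `L` in `1..L_max` whose moving
#' average removes at least a fraction `k` of the trace energy (sum of
#' squared samples): `(E_orig - E_filt(L)) / E_orig >= k`. On
#' noise-dominated traces `k = 0.02` yields `L = 2`. If no length within
#' the cap reaches the target (e.g. a constant trace, which the filter
#' preserves exactly), `L_max` is returned with a warning.
#'
#' @param current Sample series (length >= 2).
#' @param k Target attenuation fraction in `[0, 1)`.
#' @param L_max Search cap.
#' @return Integer window length.
#' @export
window_length_from_energy <- function(current, k = 0.02, L_max = 50L) {
  if (length(current) < 2L) stop("series too short", call. = FALSE)
  if (k < 0 || k >= 1) stop("k must lie in [0, 1)", call. = FALSE)
  e0 <- sum(current^2)
  if (e0 == 0) {
    stop("degenerate all-zero series: energy attenuation is undefined", call. = FALSE)
  }
  L_max <- min(as.integer(L_max), length(current))
  for (L in seq_len(L_max)) {
    eL <- sum(moving_average_filter(current, L)^2)
    if ((e0 - eL) / e0 >= k) return(L)
  }
  warning(sprintf(
    "no window length <= %d attenuates %.3g%% of the energy; returning L_max",
    L_max, 100 * k
  ), call. = FALSE)
  L_max
}

#' Command-voltage look-up table
#'
#' @param levels Target stimulation levels in mV (distinct, non-empty).
#'   Defaults to the three protocol levels 0, -45 and -80 mV.
#' @return A `voltage_lut` list.
#' @export
voltage_lut <- function(levels = c(0, -45, -80)) {
  levels <- as.numeric(levels)
  if (length(levels) == 0L || anyDuplicated(levels)) {
    stop("LUT levels must be non-empty and distinct", call. = FALSE)
  }
  structure(list(levels = levels), class = "voltage_lut")
}

#' Snap a recorded command voltage onto the theoretical levels
#'
#' Nearest-neighbour interpolation onto the protocol's look-up table:
#' each sample maps to the level minimizing the absolute difference.
#' Exact ties break toward the more negative level (deterministic rule;
#' e.g. -22.5 mV with levels 0/-45 maps to -45). Snapping is idempotent.
#'
#' @param voltage_cmd Recorded voltage series (mV).
#' @param lut A [voltage_lut()].
#' @return Series of the same length, every sample a LUT level.
#' @export
snap_voltage_to_lut <- function(voltage_cmd, lut = voltage_lut()) {
  stopifnot(inherits(lut, "voltage_lut"))
  lev <- sort(lut$levels)               # ascending: most negative first
  d <- abs(outer(as.numeric(voltage_cmd), lev, "-"))
  lev[max.col(-d, ties.method = "first")]
}

# Resolve the smoothing window for a trace under a filter_spec.
.resolve_L <- function(current, spec) {
  if (!is.null(spec$L)) return(as.integer(spec$L))
  window_length_from_energy(current, spec$k, spec$L_max)
}

#' Preprocess a sweep (smooth the current, snap the voltage)
#'
#' @param sweep A [sweep_trace()].
#' @param fspec A [filter_spec()]; a fixed `L` skips the per-trace heuristic.
#' @param lut A [voltage_lut()].
#' @return A `sweep_trace` with filtered current and snapped voltage;
#'   the window length used is attached as attribute `"L"`.
#' @export
preprocess_sweep <- function(sweep, fspec = filter_spec(), lut = voltage_lut()) {
  stopifnot(inherits(sweep, "sweep_trace"))
  L <- .resolve_L(sweep$current, fspec)
  out <- sweep_trace(
    current = moving_average_filter(sweep$current, L),
    voltage_cmd = snap_voltage_to_lut(sweep$voltage_cmd, lut),
    ts = sweep$ts
  )
  attr(out, "L") <- L
  out
}
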