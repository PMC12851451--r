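# Per-sweep feature extraction: charge areas against m-point steady-state
# baselines, peak amplitudes, and decay time constants.

#' Area/baseline configuration
#'
#' @param offset_ms Offset after a voltage transition before an
#'   integration window starts (default 2 ms, skipping the capacitive
#'   transient).
#' @param m_ca Number of trailing ROI samples averaged into the
#'   steady-state baseline of the calcium current (default 20).
#' @param m_tail Same for the tail current (default 10).
#' @return An `area_config` list.
#' @export
area_config <- function(offset_ms = 2, m_ca = 20L, m_tail = 10L) {
  stopifnot(offset_ms >= 0, m_ca >= 1, m_tail >= 1)
  structure(list(offset_ms = offset_ms, m_ca = as.integer(m_ca),
                 m_tail = as.integer(m_tail)), class = "area_config")
}

#' Steady-state baseline of a region of interest
#'
#' Arithmetic mean of the final `m` samples of the segment -- the
#' current's steady-state value, which anchors both the charge areas and
#' the peak amplitudes.
#'
#' @param segment Sample series (pA).
#' @param m Number of trailing points (`<=` segment length).
#' @return Baseline in pA.
#' @export
compute_baseline <- function(segment, m) {
  n <- length(segment)
  if (m > n) stop("segment shorter than the baseline window m", call. = FALSE)
  mean(segment[(n - m + 1L):n])
}

#' Trapezoidal charge area relative to a baseline
#'
#' Integrates `baseline - segment` over time with the trapezoidal rule,
#' so an inward (negative) current yields a positive charge magnitude.
#'
#' @param segment Sample series (pA), length >= 2.
#' @param ts_ms Sampling period in ms.
#' @param baseline Baseline level (pA).
#' @return Charge in pA*ms.
#' @export
compute_area <- function(segment, ts_ms, baseline) {
  if (length(segment) < 2L) stop("segment needs >= 2 samples", call. = FALSE)
  pracma::trapz(ts_ms * (seq_along(segment) - 1), baseline - segment)
}

.feature_names <- c("peak_cap", "peak_ca", "peak_tail", "q_ca", "q_tail",
                    "tau", "tau1", "tau2")

#' Extract the per-sweep feature set
#'
#' Orchestrates the full extraction on one sweep: smoothing and voltage
#' snapping ([prepare_sweep()]), capacitive-transient subtraction, peak
#' location ([locate_protocol_peaks()]), steady-state baselines, charge
#' areas, the single-exponential inactivation fit on the calcium decay
#' (tau) and the double-exponential fit on the tail decay (tau1 < tau2).
#'
#' ROIs: Q_Ca integrates from the later of the capacitive transient's
#' return to baseline and 2 ms after the step onset, to the step end
#' (baseline = mean of the last 20 ROI samples); Q_Tail integrates from
#' 2 ms after repolarization to the sweep end (baseline = last 10
#' samples). Peak amplitudes are reported relative to the ROI baseline
#' (inward magnitudes, positive), read as the mean of `cfg$n_average`
#' samples centered on the detected extremum. Missing peaks propagate as
#' `NA` features.
#'
#' @param sweep A [sweep_trace()].
#' @param peak_cfg A [peak_config()].
#' @param area_cfg An [area_config()].
#' @param fspec A [filter_spec()].
#' @param lut A [voltage_lut()].
#' @param features Character vector of features to compute (any of
#'   `peak_cap`, `peak_ca`, `peak_tail`, `q_ca`, `q_tail`, `tau`, `tau1`,
#'   `tau2`); restricting it skips the expensive fits.
#' @param cap_subtract Passed to [prepare_sweep()].
#' @return A one-row data.frame with columns `peak_cap_pA`, `peak_ca_pA`,
#'   `peak_tail_pA`, `q_ca_pAms`, `q_tail_pAms`, `tau_ms`, `tau1_ms`,
#'   `tau2_ms`.
#' @export
extract_sweep_features <- function(sweep,
                                   peak_cfg = peak_config(),
                                   area_cfg = area_config(),
                                   fspec = filter_spec(),
                                   lut = voltage_lut(),
                                   features = .feature_names,
                                   cap_subtract = TRUE) {
  features <- match.arg(features, .feature_names, several.ok = TRUE)
  prep <- if (inherits(sweep, "sweep_trace")) {
    prepare_sweep(sweep, fspec, lut, cap_subtract)
  } else sweep
  on <- prep$onsets
  fs <- 1e3 / prep$ts_ms
  off <- round(area_cfg$offset_ms * 1e-3 * fs)
  n <- length(prep$i_work)
  pks <- locate_protocol_peaks(prep, peak_cfg, area_cfg)
  # the causal smoothing window delays the current by (L-1)/2 samples
  # relative to the command-voltage anchors; compensate the ROI starts
  # (the ends stay clear of the next voltage edge, where the signal is
  # flat but the edge transient is not)
  d <- floor((prep$L - 1) / 2 + 0.5)

  out <- stats::setNames(rep(NA_real_, 8L),
                         c("peak_cap_pA", "peak_ca_pA", "peak_tail_pA",
                           "q_ca_pAms", "q_tail_pAms", "tau_ms",
                           "tau1_ms", "tau2_ms"))

  # calcium-current ROI: later of the capacitive transient's return to
  # baseline (judged on the unsubtracted filtered trace, where the
  # transient lives) and the 2 ms offset
  ca_end <- on$o_rep - 1L
  roi_ca <- (on$o_step + off + d):ca_end
  b_ca <- compute_baseline(prep$i_work[roi_ca], area_cfg$m_ca)
  if (!is.na(pks$peak_cap$index)) {
    b_filt <- compute_baseline(prep$i_filt[roi_ca], area_cfg$m_ca)
    after <- which(prep$i_filt[pks$peak_cap$index:ca_end] <= b_filt)
    if (length(after) > 0L) {
      cross <- pks$peak_cap$index + after[1L] - 1L
      if (cross > roi_ca[1L]) {
        roi_ca <- cross:ca_end
        b_ca <- compute_baseline(prep$i_work[roi_ca], area_cfg$m_ca)
      }
    }
  }
  roi_tail <- (on$o_rep + off + d):n
  b_tail <- compute_baseline(prep$i_work[roi_tail], area_cfg$m_tail)

  if ("peak_cap" %in% features && !is.na(pks$peak_cap$index)) {
    pre_base <- compute_baseline(prep$i_filt[(on$o_step - off - 1L):(on$o_step - 1L)],
                                 min(area_cfg$m_ca, off))
    out["peak_cap_pA"] <- pks$peak_cap$value - pre_base
  }
  if ("peak_ca" %in% features && !is.na(pks$peak_ca$index)) {
    out["peak_ca_pA"] <- b_ca - .window_mean(prep$i_work, pks$peak_ca$index,
                                             peak_cfg$n_average,
                                             lo = roi_ca[1L], hi = ca_end)
  }
  if ("peak_tail" %in% features && !is.na(pks$peak_tail$index)) {
    out["peak_tail_pA"] <- b_tail - .window_mean(prep$i_work, pks$peak_tail$index,
                                                 peak_cfg$n_average,
                                                 lo = roi_tail[1L], hi = n)
  }
  if ("q_ca" %in% features && length(roi_ca) >= 2L) {
    out["q_ca_pAms"] <- compute_area(prep$i_work[roi_ca], prep$ts_ms, b_ca)
  }
  if ("q_tail" %in% features && length(roi_tail) >= 2L) {
    out["q_tail_pAms"] <- compute_area(prep$i_work[roi_tail], prep$ts_ms, b_tail)
  }
  if ("tau" %in% features && !is.na(pks$peak_ca$index)) {
    idx <- pks$peak_ca$index:ca_end
    if (length(idx) >= 5L) {
      fit <- fit_single_exponential((idx - idx[1L]) * prep$ts_ms,
                                    prep$i_work[idx])
      if (fit$converged) out["tau_ms"] <- fit$params[["tau"]]
    }
  }
  if (any(c("tau1", "tau2") %in% features) && !is.na(pks$peak_tail$index)) {
    idx <- pks$peak_tail$index:n
    if (length(idx) >= 7L) {
      fit <- fit_double_exponential((idx - idx[1L]) * prep$ts_ms,
                                    prep$i_work[idx])
      if (fit$converged) {
        out["tau1_ms"] <- fit$params[["tau1"]]
        out["tau2_ms"] <- fit$params[["tau2"]]
      }
    }
  }
  as.data.frame(as.list(out))
}

#' Extract the feature matrix of a whole recording
#'
#' One row per sweep (the canonical protocol gives the 30 x 6 core
#' feature matrix, 180 values, plus the two auxiliary peak columns). The
#' smoothing window is resolved once per recording, on the concatenated
#' current of all sweeps, so every sweep is filtered identically.
#'
#' @param rec A [cell_recording()].
#' @inheritParams extract_sweep_features
#' @return A data.frame of class `feature_matrix` with a leading `sweep`
#'   column; the cell id and regime label are attached as attributes.
#' @export
extract_recording_features <- function(rec,
                                       peak_cfg = peak_config(),
                                       area_cfg = area_config(),
                                       fspec = filter_spec(),
                                       lut = voltage_lut(),
                                       features = .feature_names,
                                       cap_subtract = TRUE) {
  stopifnot(inherits(rec, "cell_recording"))
  if (is.null(fspec$L)) {
    L <- window_length_from_energy(
      unlist(lapply(rec$sweeps, `[[`, "current"), use.names = FALSE),
      fspec$k, fspec$L_max)
    fspec <- filter_spec(k = fspec$k, L = L, L_max = max(fspec$L_max, L))
  }
  rows <- lapply(rec$sweeps, extract_sweep_features,
                 peak_cfg = peak_cfg, area_cfg = area_cfg, fspec = fspec,
                 lut = lut, features = features, cap_subtract = cap_subtract)
  out <- cbind(sweep = seq_along(rows), do.call(rbind, rows))
  attr(out, "cell_id") <- rec$cell_id
  attr(out, "regime_label") <- rec$regime_label
  class(out) <- c("feature_matrix", class(out))
  out
}
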