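# Threshold-based peak detection (findpeaks-style semantics: height,
# prominence, interpolated half-prominence width, minimum separation) and
# the protocol-aware location of the capacitive, calcium and tail peaks.

#' Peak-detector thresholds
#'
#' Defaults follow the analysis pipeline's settings: minimum prominence
#' 10 pA, minimum height 100 pA, minimum separation 63 samples
#' (63*Ts seconds) and minimum width 1.163 samples (interpolated, so
#' non-integer widths compare exactly).
#'
#' @param min_prominence Minimum topographic prominence (pA).
#' @param min_height Minimum peak height (pA, on the analysis polarity).
#' @param min_separation_samples Minimum distance between kept peaks
#'   (samples); of two closer candidates the larger survives.
#' @param min_width_samples Minimum half-prominence width (samples).
#' @param n_average Window length (samples, odd) for the steady
#'   amplitude read-out: the reported protocol-peak amplitude is the mean
#'   of this many samples centered on the detected extremum.
#' @return A `peak_config` list.
#' @export
peak_config <- function(min_prominence = 10, min_height = 100,
                        min_separation_samples = 63,
                        min_width_samples = 1.163,
                        n_average = 9L) {
  stopifnot(min_prominence >= 0, min_height >= 0,
            min_separation_samples >= 0, min_width_samples >= 0,
            n_average >= 1)
  structure(
    list(min_prominence = min_prominence, min_height = min_height,
         min_separation_samples = min_separation_samples,
         min_width_samples = min_width_samples,
         n_average = as.integer(n_average)),
    class = "peak_config"
  )
}

# Prominence and interpolated half-prominence width of the local maximum
# at index i of series y (analysis polarity).
.peak_prominence_width <- function(y, i) {
  n <- length(y)
  # extent: walk out until a strictly higher sample or the series edge
  jl <- i
  while (jl > 1L && y[jl - 1L] <= y[i]) jl <- jl - 1L
  jr <- i
  while (jr < n && y[jr + 1L] <= y[i]) jr <- jr + 1L
  base_l <- if (jl < i) min(y[jl:(i - 1L)]) else y[i]
  base_r <- if (jr > i) min(y[(i + 1L):jr]) else y[i]
  prom <- y[i] - max(base_l, base_r)

  ref <- y[i] - prom / 2
  # left crossing of the reference level, interpolated
  xl <- jl
  if (i > jl) {
    k <- i
    while (k > jl && y[k - 1L] > ref) k <- k - 1L
    xl <- if (k == jl && y[k] > ref) jl
          else (k - 1L) + (ref - y[k - 1L]) / (y[k] - y[k - 1L])
  }
  xr <- jr
  if (i < jr) {
    k <- i
    while (k < jr && y[k + 1L] > ref) k <- k + 1L
    xr <- if (k == jr && y[k] > ref) jr
          else k + (y[k] - ref) / (y[k] - y[k + 1L])
  }
  c(prominence = prom, width = xr - xl)
}

#' Detect peaks satisfying amplitude, prominence, width and separation rules
#'
#' Candidates are samples strictly larger than both neighbours; negative
#' peaks (local minima) are found by applying the identical procedure to
#' the sign-flipped series. Filters apply in order: minimum height,
#' minimum prominence, minimum width, then minimum separation (candidates
#' sorted by height, a candidate is dropped if a larger kept peak lies
#' closer than the threshold).
#'
#' @param current Sample series (pA), length >= 3.
#' @param cfg A [peak_config()].
#' @param polarity `"positive"` for maxima, `"negative"` for minima.
#' @return A data.frame with columns `index` (1-based sample index),
#'   `value` (original signal value), `height` (value on the analysis
#'   polarity), `prominence` and `width` (samples), ordered by index.
#'   Zero rows when nothing qualifies.
#' @export
detect_peaks <- function(current, cfg = peak_config(),
                         polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (length(current) < 3L) stop("series too short for peak detection", call. = FALSE)
  y <- if (polarity == "negative") -current else current
  n <- length(y)
  i <- 2:(n - 1L)
  cand <- i[y[i] > y[i - 1L] & y[i] > y[i + 1L]]
  cand <- cand[y[cand] >= cfg$min_height]
  empty <- data.frame(index = integer(0), value = numeric(0), height = numeric(0),
                      prominence = numeric(0), width = numeric(0))
  if (length(cand) == 0L) return(empty)

  pw <- vapply(cand, function(j) .peak_prominence_width(y, j), numeric(2))
  keep <- pw["prominence", ] >= cfg$min_prominence &
    pw["width", ] >= cfg$min_width_samples
  cand <- cand[keep]; pw <- pw[, keep, drop = FALSE]
  if (length(cand) == 0L) return(empty)

  ord <- order(y[cand], decreasing = TRUE)
  kept <- integer(0)
  for (j in ord) {
    if (all(abs(cand[j] - cand[kept]) >= cfg$min_separation_samples)) {
      kept <- c(kept, j)
    }
  }
  kept <- sort(kept)
  data.frame(
    index = cand[kept],
    value = current[cand[kept]],
    height = y[cand[kept]],
    prominence = pw["prominence", kept],
    width = pw["width", kept]
  )
}

# Largest peak in a window that passes the height/prominence/width
# thresholds: candidates are scanned in descending height, so the first
# passer is exactly the peak detect_peaks() would rank highest (the
# separation rule never removes the tallest peak). One prominence walk
# instead of one per candidate.
.strongest_peak <- function(x, cfg, polarity) {
  y <- if (polarity == "negative") -x else x
  n <- length(y)
  if (n < 3L) return(NULL)
  i <- 2:(n - 1L)
  cand <- i[y[i] > y[i - 1L] & y[i] > y[i + 1L]]
  cand <- cand[y[cand] >= cfg$min_height]
  if (length(cand) == 0L) return(NULL)
  for (j in cand[order(y[cand], decreasing = TRUE)]) {
    pw <- .peak_prominence_width(y, j)
    if (pw[["prominence"]] >= cfg$min_prominence &&
        pw[["width"]] >= cfg$min_width_samples) {
      return(list(index = j, value = x[j]))
    }
  }
  NULL
}

#' Prepare a sweep for feature extraction
#'
#' Smooths the current, snaps the command voltage, locates the protocol
#' segments, and (by default) removes the capacitive/stray transients by
#' scaled subtraction of a single exponential fitted to the pre-pulse
#' passive transient: the pre-pulse step is purely passive (sodium
#' current eliminated, calcium channels still closed), so its transient,
#' scaled by the voltage-step ratio, is a noise-free template of the
#' capacitive transient riding on each subsequent step of the linear
#' circuit.
#'
#' @param sweep A [sweep_trace()].
#' @param fspec A [filter_spec()].
#' @param lut A [voltage_lut()].
#' @param cap_subtract Subtract the scaled pre-pulse transient from the
#'   depolarization and repolarization segments (default `TRUE`).
#' @return A list: `i_filt` (smoothed current), `i_work` (smoothed,
#'   transient-subtracted working trace), `v_snap`, `onsets`
#'   (`o_pre`/`o_step`/`o_rep`), `ts_ms`, `L`, and `cap_fit` (the fitted
#'   transient, `NULL` when unavailable).
#' @export
prepare_sweep <- function(sweep, fspec = filter_spec(), lut = voltage_lut(),
                          cap_subtract = TRUE) {
  stopifnot(inherits(sweep, "sweep_trace"))
  L <- .resolve_L(sweep$current, fspec)
  i_filt <- moving_average_filter(sweep$current, L)
  v_snap <- snap_voltage_to_lut(sweep$voltage_cmd, lut)
  onsets <- .protocol_onsets(v_snap)
  ts_ms <- sweep$ts * 1e3
  i_work <- i_filt
  cap_fit <- NULL
  if (cap_subtract && !is.na(onsets$o_pre)) {
    cap_fit <- fit_capacitive_transient(i_filt, onsets$o_pre, 1 / sweep$ts)
    if (!is.null(cap_fit) && cap_fit$converged) {
      dv_pre <- v_snap[onsets$o_pre] - v_snap[onsets$o_pre - 1L]
      n <- length(i_work)
      for (o in c(onsets$o_step, onsets$o_rep)) {
        dv <- v_snap[o] - v_snap[o - 1L]
        scale <- dv / dv_pre
        start <- o + cap_fit$lag
        len <- min(n, start + cap_fit$n_decay) - start + 1L
        if (len > 0L && start <= n) {
          t_rel <- (0:(len - 1L)) * ts_ms
          i_work[start:(start + len - 1L)] <-
            i_work[start:(start + len - 1L)] -
            scale * cap_fit$a * exp(-t_rel / cap_fit$tau)
        }
      }
    }
  }
  list(i_filt = i_filt, i_work = i_work, v_snap = v_snap, onsets = onsets,
       ts_ms = ts_ms, L = L, cap_fit = cap_fit)
}

# Mean of a short window centered on index i (clipped to [lo, hi]).
.window_mean <- function(x, i, n_avg, lo = 1L, hi = length(x)) {
  h <- (n_avg - 1L) %/% 2L
  mean(x[max(lo, i - h):min(hi, i + h)])
}

#' Locate the capacitive, calcium and tail peaks of a sweep
#'
#' The capacitive peak is the first positive peak after depolarization to
#' the step level (pre-pulse currents are excluded from the analysis);
#' the calcium peak is the largest negative peak inside the step window
#' starting 2 ms after the step onset; the tail peak is the
#' largest-magnitude negative excursion starting 2 ms after
#' repolarization. Ionic peaks are searched on the transient-subtracted
#' working trace. The tail decays monotonically from its window edge
#' once the capacitive transient is removed, so its peak is read as the
#' guarded window extremum rather than an interior local minimum (which
#' noise would systematically displace down the decay); the same guarded
#' fallback applies to a calcium window without interior extrema. A
#' candidate only counts if its magnitude relative to the window's
#' steady-state baseline clears the height threshold; a missing peak is
#' reported as `NA`, never fabricated.
#'
#' @param sweep A [sweep_trace()], or a prepared sweep from
#'   [prepare_sweep()].
#' @param cfg A [peak_config()].
#' @param area_cfg An [area_config()] (supplies the 2 ms offset).
#' @param ... Passed on to [prepare_sweep()] when `sweep` is raw.
#' @return A list with elements `peak_cap`, `peak_ca`, `peak_tail`, each
#'   a list of `index` and `value` (`NA` when absent).
#' @export
locate_protocol_peaks <- function(sweep, cfg = peak_config(),
                                  area_cfg = area_config(), ...) {
  prep <- if (inherits(sweep, "sweep_trace")) prepare_sweep(sweep, ...) else sweep
  on <- prep$onsets
  fs <- 1e3 / prep$ts_ms
  off <- round(area_cfg$offset_ms * 1e-3 * fs)
  n <- length(prep$i_filt)
  miss <- list(index = NA_integer_, value = NA_real_)

  pick <- function(x, lo, hi, polarity, first = FALSE, m_base = 0L,
                   extremum = FALSE) {
    lo <- max(1L, lo); hi <- min(n, hi)
    if (hi - lo + 1L < 3L) return(miss)
    win <- x[lo:hi]
    best <- if (extremum) {
      NULL                               # go straight to the guarded extremum
    } else if (first) {
      pk <- detect_peaks(win, cfg, polarity)
      if (nrow(pk) > 0L) list(index = pk$index[1L], value = pk$value[1L]) else NULL
    } else {
      .strongest_peak(win, cfg, polarity)
    }
    if (is.null(best)) {
      if (polarity == "negative" && m_base > 0L && length(win) >= m_base) {
        # window extremum, accepted only if it clears the height
        # threshold relative to the steady-state baseline
        i <- which.min(win)
        if (compute_baseline(win, m_base) - win[i] >= cfg$min_height) {
          return(list(index = lo + i - 1L, value = win[i]))
        }
      }
      return(miss)
    }
    list(index = lo + best$index - 1L, value = best$value)
  }

  # compensate the causal smoothing delay in the search windows
  d <- floor((prep$L - 1) / 2 + 0.5)
  cap_hi <- min(on$o_step + max(off, round(5e-3 * fs)) + d, on$o_rep - 1L)
  list(
    peak_cap = pick(prep$i_filt, on$o_step, cap_hi, "positive", first = TRUE),
    peak_ca = pick(prep$i_work, on$o_step + off + d, on$o_rep - 1L, "negative",
                   m_base = area_cfg$m_ca),
    # after transient subtraction the tail decays monotonically from the
    # window edge, so its peak is the guarded window extremum: interior
    # local minima of the noisy decay would systematically under-read it
    peak_tail = pick(prep$i_work, on$o_rep + off + d, n, "negative",
                     m_base = area_cfg$m_tail, extremum = TRUE)
  )
}
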