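# Exponential decay fitting (single and double), AIC-based model
# selection, and the capacitive-transient fit used for P/N-style
# subtraction.

#' Least-squares AIC
#'
#' AIC in its least-squares form, `n * log(rss/n) + 2k`, appropriate for
#' Gaussian residual models when only AIC differences matter. A zero (or
#' negative) residual sum of squares cannot be scored; a large negative
#' sentinel is returned with attribute `degenerate = TRUE` so a perfect
#' fit always wins model selection without producing `-Inf`.
#'
#' @param rss Residual sum of squares (pA^2).
#' @param n Number of samples (`> k`).
#' @param k Number of estimated parameters.
#' @return AIC value (dimensionless).
#' @export
compute_aic <- function(rss, n, k) {
  stopifnot(n > k)
  if (!is.finite(rss) || rss <= 0) {
    return(structure(-1e300, degenerate = TRUE))
  }
  n * log(rss / n) + 2 * k
}

.fit_result <- function(model, params, rss, n, k, converged,
                        degenerate = FALSE) {
  structure(
    list(
      model = model, params = params, rss = rss, n = n, k_params = k,
      aic = if (converged) compute_aic(rss, n, k) else NA_real_,
      converged = converged, degenerate = degenerate
    ),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<exp_fit> %s exponential: not converged\n", x$model))
  } else {
    cat(sprintf("<exp_fit> %s exponential: %s | rss = %.4g, AIC = %.4g (k = %d)%s\n",
                x$model,
                paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", "),
                x$rss, as.numeric(x$aic), x$k_params,
                if (x$degenerate) " [degenerate]" else ""))
  }
  invisible(x)
}

# Fast single-exponential fit by variable projection: for fixed tau the
# model a*exp(-t/tau) + c is linear in (a, c), so the profiled RSS is
# minimized over log(tau) alone. Used where speed matters (per-sweep
# transient templates); the general-purpose op is fit_single_exponential.
.fit_exp_varpro <- function(t, y, tau_range = NULL) {
  n <- length(y)
  span <- t[n] - t[1L]
  if (is.null(tau_range)) tau_range <- c(span / 200, span * 5)
  rss_of <- function(log_tau) {
    e <- exp(-(t - t[1L]) / exp(log_tau))
    fit <- stats::lm.fit(cbind(e, 1), y)
    sum(fit$residuals^2)
  }
  opt <- stats::optimize(rss_of, log(tau_range))
  tau <- exp(opt$minimum)
  e <- exp(-(t - t[1L]) / tau)
  fit <- stats::lm.fit(cbind(e, 1), y)
  list(a = fit$coefficients[[1L]], tau = tau, c = fit$coefficients[[2L]],
       t0 = t[1L], rss = sum(fit$residuals^2),
       converged = is.finite(tau) && tau > 0 &&
         tau > tau_range[1L] * 1.001 && tau < tau_range[2L] * 0.999)
}

# Shared nlsLM wrapper: returns NULL on failure instead of throwing.
.try_nls <- function(formula, data, start, lower) {
  tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      formula, data = data, start = start, lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-10,
                                           ptol = 1e-10)
    )),
    error = function(e) NULL
  )
}

#' Fit a single-exponential decay
#'
#' Least-squares fit of `y = a * exp(-(t - t0)/tau) + c` with the segment
#' origin `t0` fixed at the first fitted sample (the conventional
#' parameter count of this model, k = 4, is used in the AIC).
#' Initialization: offset from the trailing samples, amplitude from the
#' first sample, tau from the 1/e crossing. A flat or pathological
#' segment yields `converged = FALSE` (never an exception), as does a
#' non-positive fitted tau.
#'
#' @param t Time vector (ms), starting at the fitted segment's origin.
#' @param y Current samples (pA), same length (`>= 5`).
#' @return An `exp_fit` with params `a`, `tau` (ms), `c`, `t0`.
#' @export
fit_single_exponential <- function(t, y) {
  n <- length(y)
  if (n < 5L || length(t) != n) {
    stop("need >= 5 samples with matching time vector", call. = FALSE)
  }
  t0 <- t[1L]
  s <- t - t0
  c0 <- mean(y[max(1L, n - max(5L, n %/% 20L)):n])
  a0 <- y[1L] - c0
  fail <- .fit_result("single", c(a = NA_real_, tau = NA_real_, c = NA_real_,
                                  t0 = t0), NA_real_, n, 4L, FALSE)
  if (abs(a0) < .Machine$double.eps * 100) return(fail)
  idx_e <- which(abs(y - c0) <= abs(a0) / exp(1))
  tau0 <- if (length(idx_e) > 0L) max(s[idx_e[1L]], s[2L]) else s[n] / 3
  fit <- .try_nls(y ~ a * exp(-s / tau) + c, data.frame(s = s, y = y),
                  start = list(a = a0, tau = tau0, c = c0),
                  lower = c(a = -Inf, tau = 1e-9, c = -Inf))
  if (is.null(fit)) return(fail)
  p <- stats::coef(fit)
  if (!is.finite(p[["tau"]]) || p[["tau"]] <= 0) return(fail)
  .fit_result("single",
              c(a = p[["a"]], tau = p[["tau"]], c = p[["c"]], t0 = t0),
              sum(stats::resid(fit)^2), n, 4L, TRUE)
}

#' Fit a double-exponential decay
#'
#' Least-squares fit of `y = a1 * exp(-t/tau1) + a2 * exp(-t/tau2) + c`
#' (k = 5), seeded from the single-exponential fit (`tau/3` and `3*tau`,
#' amplitudes split 70/30). Time constants are returned sorted
#' (`tau1 < tau2`, amplitudes permuted accordingly). Nearly equal fitted
#' time constants mark the result `degenerate` (the two components are
#' not identifiable).
#'
#' @param t Time vector (ms), starting at the fitted segment's origin.
#' @param y Current samples (pA), same length (`>= 7`).
#' @return An `exp_fit` with params `a1`, `tau1`, `a2`, `tau2`, `c`, `t0`.
#' @export
fit_double_exponential <- function(t, y) {
  n <- length(y)
  if (n < 7L || length(t) != n) {
    stop("need >= 7 samples with matching time vector", call. = FALSE)
  }
  t0 <- t[1L]
  s <- t - t0
  single <- fit_single_exponential(t, y)
  fail <- .fit_result("double", c(a1 = NA_real_, tau1 = NA_real_,
                                  a2 = NA_real_, tau2 = NA_real_,
                                  c = NA_real_, t0 = t0), NA_real_, n, 5L, FALSE)
  if (single$converged) {
    a0 <- single$params[["a"]]; tau0 <- single$params[["tau"]]
    c0 <- single$params[["c"]]
  } else {
    c0 <- mean(y[max(1L, n - 5L):n]); a0 <- y[1L] - c0; tau0 <- s[n] / 3
    if (abs(a0) < .Machine$double.eps * 100) return(fail)
  }
  fit <- .try_nls(
    y ~ a1 * exp(-s / tau1) + a2 * exp(-s / tau2) + c,
    data.frame(s = s, y = y),
    start = list(a1 = 0.7 * a0, tau1 = tau0 / 3, a2 = 0.3 * a0,
                 tau2 = 3 * tau0, c = c0),
    lower = c(a1 = -Inf, tau1 = 1e-9, a2 = -Inf, tau2 = 1e-9, c = -Inf)
  )
  if (is.null(fit)) return(fail)
  p <- stats::coef(fit)
  taus <- c(p[["tau1"]], p[["tau2"]])
  amps <- c(p[["a1"]], p[["a2"]])
  if (any(!is.finite(taus)) || any(taus <= 0)) return(fail)
  o <- order(taus)
  taus <- taus[o]; amps <- amps[o]
  # non-identifiable: the two components collapse onto one time constant,
  # or one of them carries (essentially) no amplitude
  degen <- (taus[2L] - taus[1L]) / taus[2L] < 1e-2 ||
    min(abs(amps)) <= 1e-6 * sum(abs(amps))
  .fit_result("double",
              c(a1 = amps[1L], tau1 = taus[1L], a2 = amps[2L], tau2 = taus[2L],
                c = p[["c"]], t0 = t0),
              sum(stats::resid(fit)^2), n, 5L, TRUE, degenerate = degen)
}

#' Select the tail-current decay model by AIC
#'
#' Fits both the single- and the double-exponential model and returns the
#' one with the smaller AIC (ties favour the simpler model). If neither
#' fit converges the result is a non-converged `exp_fit` flagging the
#' feature as missing.
#'
#' @param t Time vector (ms).
#' @param y Current samples (pA).
#' @return An `exp_fit` (the winning model), with the losing model's AIC
#'   attached as attribute `"aic_other"`.
#' @export
select_tail_model <- function(t, y) {
  f1 <- fit_single_exponential(t, y)
  f2 <- fit_double_exponential(t, y)
  if (!f1$converged && !f2$converged) return(f1)
  if (!f2$converged) return(f1)
  if (!f1$converged) return(f2)
  if (as.numeric(f2$aic) < as.numeric(f1$aic)) {
    structure(f2, aic_other = as.numeric(f1$aic))
  } else {
    structure(f1, aic_other = as.numeric(f2$aic))
  }
}

#' Fit the passive transient after a protocol step
#'
#' Finds the extremum of the smoothed current within a short window after
#' the step onset and fits `a * exp(-t/tau) + c` to its decay. The first
#' `settle_ms` after the extremum are excluded from the fit (there the
#' acquisition filter still shapes the edge, which would bias tau) and
#' the amplitude is extrapolated back to the extremum. Used by
#' [prepare_sweep()] to build the subtraction template for the
#' capacitive transients of the linear circuit.
#'
#' @param i_filt Smoothed current series (pA).
#' @param onset First sample index of the new voltage level.
#' @param fs Sampling frequency (Hz).
#' @param window_ms Fit window after the onset (default 4 ms, several
#'   membrane charging time constants).
#' @param settle_ms Initial span excluded from the fit (default 0.5 ms).
#' @return A list `a` (amplitude at the extremum), `tau` (ms), `c`,
#'   `lag` (samples from onset to the transient extremum), `n_decay`
#'   (samples over which the template is meaningful), `converged`; or
#'   `NULL` if the window leaves the trace.
#' @export
fit_capacitive_transient <- function(i_filt, onset, fs, window_ms = 4,
                                     settle_ms = 0.5) {
  n <- length(i_filt)
  hi <- onset + round(window_ms * 1e-3 * fs)
  if (onset < 2L || hi > n) return(NULL)
  seg <- i_filt[onset:hi]
  pk <- which.max(abs(seg - seg[length(seg)]))
  skip <- round(settle_ms * 1e-3 * fs)
  lo <- onset + pk - 1L + skip
  if (hi - lo + 1L < 5L) return(NULL)
  ts_ms <- 1e3 / fs
  t <- (lo:hi - (onset + pk - 1L)) * ts_ms        # origin at the extremum
  fit <- .fit_exp_varpro(t, i_filt[lo:hi])
  if (!fit$converged) {
    return(list(a = NA_real_, tau = NA_real_, c = NA_real_, lag = pk - 1L,
                n_decay = 0L, converged = FALSE))
  }
  tau <- fit$tau
  a0 <- fit$a * exp(fit$t0 / tau)                 # back to t = 0
  list(
    a = a0, tau = tau, c = fit$c,
    lag = pk - 1L,
    n_decay = as.integer(ceiling(10 * tau / ts_ms)),
    converged = TRUE
  )
}
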