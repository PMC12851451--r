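# Zero-order electrical model of the whole-cell patch-clamp experiment:
# one-compartment passive cell behind the access resistance, a seal shunt,
# an ideal transimpedance amplifier, and a Bessel acquisition filter.

#' Electrical parameters of the patch-clamp circuit
#'
#' Defaults are the nominal values of the simulated experiment: membrane
#' capacitance 55 pF, membrane resistance 500 MOhm, resting potential
#' -90 mV, access resistance 15 MOhm, seal resistance 1 GOhm, feedback
#' resistance 500 MOhm ("Medium" gain range, modeled as an ideal
#' transimpedance stage), with negligible feedback/pipette capacitance
#' and pipette resistance.
#'
#' @param Cm Membrane capacitance (F).
#' @param Rm Membrane resistance (Ohm).
#' @param vm_rest Resting membrane potential (mV).
#' @param Ra Access resistance (Ohm).
#' @param Rs Seal resistance (Ohm).
#' @param Rf Feedback resistance (Ohm); bookkeeping only under the ideal
#'   amplifier assumption.
#' @param Cf Feedback capacitance (F).
#' @param Rp Pipette resistance (Ohm).
#' @param Cp Pipette capacitance (F).
#' @return A `circuit_params` list.
#' @export
circuit_params <- function(Cm = 55e-12, Rm = 500e6, vm_rest = -90,
                           Ra = 15e6, Rs = 1e9, Rf = 500e6, Cf = 0,
                           Rp = 0, Cp = 0) {
  stopifnot(Cm >= 0, Cf >= 0, Cp >= 0, Rm > 0, Ra > 0, Rs > 0, Rf > 0, Rp >= 0)
  structure(
    list(Cm = Cm, Rm = Rm, vm_rest = vm_rest, Ra = Ra, Rs = Rs,
         Rf = Rf, Cf = Cf, Rp = Rp, Cp = Cp),
    class = "circuit_params"
  )
}

#' Membrane charging time constant of the clamped circuit
#'
#' `tau_cap = Cm * (Ra * Rm) / (Ra + Rm)` -- the decay constant of the
#' capacitive transient elicited by a command step (about 0.80 ms at the
#' default parameters).
#'
#' @param circuit A [circuit_params()].
#' @return Time constant in seconds.
#' @export
capacitive_tau <- function(circuit) {
  with(circuit, Cm * Ra * Rm / (Ra + Rm))
}

#' Stimulation protocol specification
#'
#' The canonical pulse: hold at -80 mV, a 50 ms pre-pulse to -45 mV (to
#' inactivate sodium current), a 200 ms depolarization to 0 mV (eliciting
#' I_Ca), then return to -80 mV (eliciting the tail current); repeated
#' `n_sweeps` times at `stim_freq`. One sweep spans `1/stim_freq` seconds
#' (`round(fs/stim_freq)` samples).
#'
#' @param v_hold,v_prepulse,v_step Holding, pre-pulse and step levels (mV).
#' @param t_hold Hold duration before the pre-pulse (ms).
#' @param t_prepulse,t_step Pre-pulse and step durations (ms).
#' @param n_sweeps Number of protocol repetitions (canonical 30).
#' @param stim_freq Stimulation frequency (Hz, protocol range 0.5--2).
#' @param fs Sampling frequency (Hz, ADC maximum 200 kHz).
#' @return A `protocol_spec` list.
#' @export
protocol_spec <- function(v_hold = -80, v_prepulse = -45, v_step = 0,
                          t_hold = 100, t_prepulse = 50, t_step = 200,
                          n_sweeps = 30L, stim_freq = 1, fs = 10e3) {
  stopifnot(t_hold >= 0, t_prepulse >= 0, t_step > 0, n_sweeps >= 1,
            stim_freq > 0, fs > 0)
  if (fs > 200e3) stop("fs exceeds the 200 kHz ADC maximum", call. = FALSE)
  if ((t_hold + t_prepulse + t_step) / 1e3 >= 1 / stim_freq) {
    stop("pulse longer than the inter-stimulus interval", call. = FALSE)
  }
  structure(
    list(v_hold = v_hold, v_prepulse = v_prepulse, v_step = v_step,
         t_hold = t_hold, t_prepulse = t_prepulse, t_step = t_step,
         n_sweeps = as.integer(n_sweeps), stim_freq = stim_freq, fs = fs),
    class = "protocol_spec"
  )
}

#' Build the command-voltage waveform of one sweep
#'
#' Piecewise-constant series: `v_hold` for `t_hold`, `v_prepulse` for
#' `t_prepulse`, `v_step` for `t_step`, then `v_hold` until the end of the
#' inter-stimulus interval. At the defaults (10 kHz, 1 Hz) this is 10 000
#' samples with 500 at -45 mV and 2000 at 0 mV.
#'
#' @param spec A [protocol_spec()].
#' @return Numeric mV series of length `round(fs/stim_freq)`.
#' @export
build_protocol_waveform <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  n <- round(spec$fs / spec$stim_freq)
  smp <- function(ms) round(ms * 1e-3 * spec$fs)
  n_hold <- smp(spec$t_hold)
  n_pre <- smp(spec$t_prepulse)
  n_step <- smp(spec$t_step)
  v <- rep(spec$v_hold, n)
  if (n_pre > 0L) v[(n_hold + 1L):(n_hold + n_pre)] <- spec$v_prepulse
  v[(n_hold + n_pre + 1L):(n_hold + n_pre + n_step)] <- spec$v_step
  v
}

#' Simulate the passive (capacitive + leak) pipette current
#'
#' Voltage-clamp response of the one-compartment circuit: the command
#' `v_cmd` drives the membrane RC (`Rm` parallel `Cm`, resting EMF
#' `vm_rest`) through the access resistance `Ra`, with the seal `Rs`
#' shunting the pipette node to bath. The membrane potential obeys
#' `Cm dVm/dt = (v_cmd - Vm)/Ra - (Vm - vm_rest)/Rm` and the pipette
#' current is `(v_cmd - Vm)/Ra + v_cmd/Rs`. Because the command is
#' piecewise constant the update is computed exactly per constant segment
#' (exponential relaxation towards the segment's steady state with
#' [capacitive_tau()]), so a command step `dV` produces the textbook
#' transient of initial amplitude `dV/Ra` (plus the seal jump `dV/Rs`)
#' relaxing onto the steady state `dV/(Ra + Rm)`.
#'
#' @param v_cmd Command-voltage series (mV, uniform grid).
#' @param circuit A [circuit_params()].
#' @param fs Sampling frequency (Hz).
#' @param vm0 Initial membrane potential (mV); defaults to the steady
#'   state under the first command sample.
#' @return Pipette current series (pA).
#' @export
simulate_passive_current <- function(v_cmd, circuit = circuit_params(),
                                     fs, vm0 = NULL) {
  stopifnot(inherits(circuit, "circuit_params"), fs > 0)
  v <- as.numeric(v_cmd) * 1e-3                      # volts
  ts <- 1 / fs
  tau <- capacitive_tau(circuit)
  vrest <- circuit$vm_rest * 1e-3
  Ra <- circuit$Ra; Rm <- circuit$Rm; Rs <- circuit$Rs
  v_inf <- function(vp) (vp * Rm + vrest * Ra) / (Ra + Rm)

  seg <- rle(v)
  vm_start <- if (is.null(vm0)) v_inf(seg$values[1L]) else vm0 * 1e-3
  vm <- numeric(length(v))
  pos <- 0L
  for (s in seq_along(seg$values)) {
    len <- seg$lengths[s]
    vinf <- v_inf(seg$values[s])
    t_rel <- (0:(len - 1L)) * ts
    vm_seg <- vinf + (vm_start - vinf) * exp(-t_rel / tau)
    vm[pos + seq_len(len)] <- vm_seg
    # state at the *next* sample time (one full step beyond the last sample)
    vm_start <- vinf + (vm_start - vinf) * exp(-len * ts / tau)
    pos <- pos + len
  }
  ((v - vm) / Ra + v / Rs) * 1e12                    # pA
}

#' Acquisition low-pass filter specification (Bessel)
#'
#' @param order Filter order (default 4, the amplifier's setting).
#' @param cutoff_hz -3 dB cutoff (Hz). The amplifier's typology and order
#'   are fixed by the hardware; the cutoff is configurable and defaults to
#'   2.9 kHz, a standard whole-cell acquisition bandwidth.
#' @param ladder Optional named list of passive ladder components kept for
#'   provenance; the filter itself is designed from the analytic Bessel
#'   prototype.
#' @return A `bessel_filter_spec` list.
#' @export
bessel_filter_spec <- function(order = 4L, cutoff_hz = 2900, ladder = NULL) {
  stopifnot(order >= 1, cutoff_hz > 0)
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz, ladder = ladder),
            class = "bessel_filter_spec")
}

# Poles of the analog Bessel low-pass prototype, normalized so the -3 dB
# point sits at omega = 1 rad/s. Coefficients of the reverse Bessel
# polynomial theta_n via the closed form a_k = (2n-k)! / (2^(n-k) k! (n-k)!).
.bessel_prototype_poles <- function(order) {
  k <- 0:order
  a <- factorial(2 * order - k) / (2^(order - k) * factorial(k) * factorial(order - k))
  poles <- polyroot(a)                                  # increasing powers
  mag2 <- function(w) abs(sum(a * (1i * w)^k))^2
  # |H(jw)|^2 = a0^2 / |theta(jw)|^2 ; -3 dB where |theta(jw)|^2 = 2 a0^2
  w3 <- stats::uniroot(function(w) mag2(w) - 2 * a[1L]^2,
                       interval = c(1e-6, 10 * order))$root
  poles / w3
}

#' Apply the Bessel acquisition filter
#'
#' Discretizes the analog Bessel prototype with the bilinear transform
#' (cutoff prewarped) and applies it causally, with the filter state
#' initialized at rest on the first sample so a constant input passes
#' unchanged. DC gain is normalized to 1 (within 1e-6); the maximally
#' flat group delay gives the characteristic near-monotone step response
#' (< 1% overshoot at order 4).
#'
#' @param current Input series (pA).
#' @param spec A [bessel_filter_spec()].
#' @param fs Sampling frequency (Hz); `cutoff_hz` must be below `fs/2`.
#' @return Filtered series, same length.
#' @export
apply_bessel_filter <- function(current, spec = bessel_filter_spec(), fs) {
  stopifnot(inherits(spec, "bessel_filter_spec"))
  if (spec$cutoff_hz >= fs / 2) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  wc <- 2 * fs * tan(pi * spec$cutoff_hz / fs)          # prewarped analog cutoff
  p <- .bessel_prototype_poles(spec$order) * wc
  zpg <- signal::bilinear(Sz = numeric(0), Sp = p, Sg = Re(prod(-p)), T = 1 / fs)
  arma <- signal::as.Arma(zpg)
  b <- Re(arma$b); a <- Re(arma$a)
  b <- b * (sum(a) / sum(b))                            # exact unit DC gain
  x0 <- current[1L]
  y <- signal::filter(signal::Arma(b = b, a = a), current - x0)
  as.numeric(y) + x0
}
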