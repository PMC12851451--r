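test_that("protocol waveform has the prescribed segment sample counts", {
  v <- build_protocol_waveform(protocol_spec())     # 10 kHz, 1 Hz
  expect_length(v, 10000L)
  expect_identical(sum(v == -45), 500L)
  expect_identical(sum(v == 0), 2000L)
  expect_true(all(unique(v) %in% c(-80, -45, 0)))

  v2 <- build_protocol_waveform(protocol_spec(t_prepulse = 0))
  expect_false(any(v2 == -45))
  expect_error(protocol_spec(stim_freq = 4), "inter-stimulus")
  expect_error(protocol_spec(fs = 250e3), "200 kHz")
})

test_that("passive response matches the closed-form RC step values", {
  circ <- circuit_params()
  fs <- 100e3
  v <- c(rep(-80, 2000), rep(-45, 8000))
  i <- simulate_passive_current(v, circ, fs)
  # before the step: equilibrium leak only (constant)
  expect_lt(diff(range(i[100:2000])), 1e-9)
  # instantaneous jump: dV/Ra + dV/Rs on top of the pre-step leak
  dv <- 35e-3
  jump <- dv / circ$Ra + dv / circ$Rs
  expect_rel_equal((i[2001] - i[2000]) * 1e-12, jump, 1e-9)
  # transient decays with tau_cap = Cm (Ra || Rm) ~ 0.80 ms
  tau <- capacitive_tau(circ)
  expect_rel_equal(tau, 55e-12 * (15e6 * 500e6) / (515e6), 1e-12)
  i_inf <- i[10000]
  k <- 2001 + round(tau * fs)          # one time constant after the step
  expect_rel_equal(i[k] - i_inf, (i[2001] - i_inf) * exp(-(k - 2001) / (tau * fs)),
                   1e-6)
  # doubling Cm doubles the decay constant but not the initial jump
  i2 <- simulate_passive_current(v, circuit_params(Cm = 110e-12), fs)
  expect_rel_equal(i2[2001] - i2[2000], i[2001] - i[2000], 1e-9)

  # constant command at equilibrium: leak only, no transient
  i0 <- simulate_passive_current(rep(-80, 500), circ, fs)
  expect_lt(max(abs(i0 - i0[1])), 1e-9)
})

test_that("passive simulation agrees with stiff ODE integration to 0.1%", {
  skip_if_not_installed("deSolve")
  circ <- circuit_params()
  fs <- 100e3
  prot <- protocol_spec(fs = fs, t_hold = 20)
  v <- build_protocol_waveform(prot)[1:40000]
  i_pkg <- simulate_passive_current(v, circ, fs)
  v_fun <- stats::approxfun(seq_along(v) / fs - 1 / fs, v * 1e-3,
                            method = "constant", rule = 2)
  rhs <- function(t, y, p) {
    vp <- v_fun(t)
    list((vp - y[1]) / (circ$Ra * circ$Cm) -
           (y[1] - circ$vm_rest * 1e-3) / (circ$Rm * circ$Cm))
  }
  times <- seq_along(v) / fs - 1 / fs
  sol <- deSolve::lsoda(y = c(vm = (-80e-3 * circ$Rm + circ$vm_rest * 1e-3 * circ$Ra) /
                                (circ$Ra + circ$Rm)),
                        times = times, func = rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  i_ode <- ((v * 1e-3 - sol[, "vm"]) / circ$Ra + v * 1e-3 / circ$Rs) * 1e12
  expect_lt(max(abs(i_pkg - i_ode)) / max(abs(i_pkg)), 1e-3)
})

test_that("passive and ionic currents superpose exactly through the chain", {
  prot <- quick_protocol()
  fs <- prot$fs
  v <- build_protocol_waveform(prot)
  bes <- bessel_filter_spec()
  p <- simulate_passive_current(v, circuit_params(), fs)
  ion <- synthesize_ionic_currents(v, ionic_params(), fs)$current
  lhs <- apply_bessel_filter(p, bes, fs) + apply_bessel_filter(ion, bes, fs)
  rhs <- apply_bessel_filter(p + ion, bes, fs)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-9)
})

test_that("Bessel filter: unit DC gain, near-monotone step, strong stopband", {
  fs <- 200e3
  spec <- bessel_filter_spec(cutoff_hz = 2900)
  const <- rep(123.4, 3000)
  expect_lt(max(abs(apply_bessel_filter(const, spec, fs) - 123.4)), 1e-6 * 123.4)

  step <- c(rep(0, 500), rep(1, 8000))
  y <- apply_bessel_filter(step, spec, fs)
  expect_lt(max(y) - 1, 0.01)                       # < 1% overshoot
  expect_rel_equal(y[8000], 1, 1e-6)

  t <- seq_len(40000) / fs
  sine <- sin(2 * pi * 29e3 * t)                    # 10x cutoff
  ys <- apply_bessel_filter(sine, spec, fs)
  atten_db <- 20 * log10(stats::sd(ys[20001:40000]) / stats::sd(sine[20001:40000]))
  expect_lt(atten_db, -40)
  expect_error(apply_bessel_filter(sine, bessel_filter_spec(cutoff_hz = 150e3), fs),
               "Nyquist")
})

test_that("noise model: identity at zero, reproducible, calibrated SD", {
  x <- sin(seq(0, 10, length.out = 1e5))
  expect_identical(add_gaussian_noise(x, noise_model(sigma_noise = 0)), x)
  n1 <- add_gaussian_noise(x, noise_model(seed = 7))
  n2 <- add_gaussian_noise(x, noise_model(seed = 7))
  expect_identical(n1, n2)
  # sigma_noise is a variance: added noise SD = sqrt(188) within 2% at n = 1e5
  expect_rel_equal(stats::sd(n1 - x), sqrt(188), 0.02)
})

test_that("ionic waveforms honor their analytic structure", {
  prot <- quick_protocol()
  v <- build_protocol_waveform(prot)
  # instantaneous activation: extremum is exactly -peak_ca at step onset
  ion0 <- synthesize_ionic_currents(v, ionic_params(tau_act = 0), prot$fs)
  expect_equal(min(ion0$current), -1800)
  on <- which(v == 0)[1]
  expect_equal(ion0$current[on], -1800)
  # amp1_frac = 1 leaves a pure single-exponential tail
  ion1 <- synthesize_ionic_currents(
    v, ionic_params(amp1_frac = 1 - 1e-12), prot$fs)$current
  rep_on <- which(v == 0)[sum(v == 0)] + 1L
  tail_seg <- -ion1[rep_on:(rep_on + 100)]
  ratios <- tail_seg[-1] / tail_seg[-length(tail_seg)]
  expect_lt(diff(range(ratios)), 1e-6)              # constant decay ratio
  expect_error(ionic_params(tau1 = 50, tau2 = 40), "tau1")
})

test_that("trapezoidal tail charge converges to the analytic integral", {
  ip <- ionic_params()
  q_inf <- analytic_tail_charge(ip)
  expect_equal(q_inf, 600 * (0.65 * 4 + 0.35 * 40))
  err <- vapply(c(2e3, 4e3, 8e3), function(fs) {
    t <- seq(0, 600, by = 1e3 / fs)
    y <- -ip$peak_tail * (ip$amp1_frac * exp(-t / ip$tau1) +
                            (1 - ip$amp1_frac) * exp(-t / ip$tau2))
    abs(compute_area(y, 1e3 / fs, 0) - q_inf)
  }, numeric(1))
  # trapezoid is second-order: halving the step divides the error by ~4
  expect_gt(err[1] / err[2], 3.5)
  expect_gt(err[2] / err[3], 3.5)
})

test_that("generated cells obey the alternation phase rule", {
  prot <- quick_protocol(n_sweeps = 6L)
  cell0 <- generate_cell(protocol = prot, noise = noise_model(0, 0))
  for (s in 2:6) expect_identical(cell0$recording$sweeps[[s]]$current,
                                  cell0$recording$sweeps[[1]]$current)
  expect_identical(cell0$recording$regime_label, "uniform")

  cell <- generate_cell(protocol = prot, alternation = alternation_model(0.3),
                        noise = noise_model(0, 0))
  q_ca <- cell$truth$q_ca
  q_tail <- cell$truth$q_tail
  expect_true(all(diff(q_ca) != 0))
  expect_true(all(sign(diff(q_ca)) == rep(c(1, -1), length.out = 5)))
  # out of phase: a large calcium charge pairs with a small tail charge
  expect_true(all(sign(diff(q_ca)) == -sign(diff(q_tail))))
  expect_identical(cell$recording$regime_label, "alternant")
})

test_that("dataset generation is labelled, counted and seed-deterministic", {
  prot <- quick_protocol(n_sweeps = 2L)
  d1 <- generate_dataset(3, 2, seed = 42, protocol = prot)
  expect_length(d1, 5L)
  labels <- vapply(d1, `[[`, character(1), "regime_label")
  expect_identical(sum(labels == "uniform"), 3L)
  expect_identical(sum(labels == "alternant"), 2L)
  d2 <- generate_dataset(3, 2, seed = 42, protocol = prot)
  expect_identical(d1[[4]]$sweeps[[1]]$current, d2[[4]]$sweeps[[1]]$current)
  d3 <- generate_dataset(3, 2, seed = 43, protocol = prot)
  expect_false(identical(d1[[4]]$sweeps[[1]]$current, d3[[4]]$sweeps[[1]]$current))
  expect_length(generate_dataset(0, 0, seed = 1, protocol = prot), 0L)
})
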