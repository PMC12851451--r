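test_that("peak detector applies the four threshold rules", {
  cfg <- peak_config()
  # triangular bump, height 500, half-width ~10 samples
  bump <- function(h, w, at, n) {
    x <- numeric(n)
    x[at + seq(-w, w)] <- h * (1 - abs(seq(-w, w)) / w)
    x
  }
  x <- bump(500, 10, 50, 120)
  pk <- detect_peaks(x, cfg)
  expect_identical(pk$index, 50L)
  expect_equal(pk$value, 500)
  # below the 100 pA height floor: nothing
  expect_identical(nrow(detect_peaks(bump(50, 10, 50, 120), cfg)), 0L)
  # two peaks 30 samples apart (< 63): only the larger survives
  x2 <- bump(500, 10, 40, 160) + bump(400, 10, 70, 160)
  pk2 <- detect_peaks(x2, cfg)
  expect_identical(pk2$index, 40L)
  # negative polarity mirrors the procedure on the flipped trace
  pk3 <- detect_peaks(-x, cfg, polarity = "negative")
  expect_identical(pk3$index, 50L)
  expect_equal(pk3$value, -500)
  expect_error(detect_peaks(c(1, 2), cfg), "too short")
})

test_that("peak detector agrees with the brute-force oracle on random traces", {
  cfg <- peak_config(min_prominence = 0.3, min_height = 0.5,
                     min_separation_samples = 6, min_width_samples = 1.1)
  withr::with_seed(2024, {
    for (trial in 1:200) {
      n <- sample(30:150, 1)
      x <- cumsum(rnorm(n)) + 2 * sin(seq_len(n) / 5)
      pol <- sample(c("positive", "negative"), 1)
      got <- detect_peaks(x, cfg, pol)$index
      want <- as.integer(bf_find_peaks(x, cfg, pol))
      expect_identical(got, want)
    }
  })
})

test_that("protocol peaks appear in capacitive -> calcium -> tail order", {
  sim <- simulate_sweep(protocol = quick_protocol(), noise = noise_model(seed = 4))
  pk <- locate_protocol_peaks(sim$sweep)
  expect_true(pk$peak_cap$index < pk$peak_ca$index)
  expect_true(pk$peak_ca$index < pk$peak_tail$index)
  expect_gt(pk$peak_cap$value, 0)
  expect_lt(pk$peak_ca$value, 0)
  # the pre-pulse capacitive spike is never reported: the first reported
  # peak lies at/after the 0 mV onset
  prep <- prepare_sweep(sim$sweep)
  expect_gte(pk$peak_cap$index, prep$onsets$o_step)

  # zeroed ionic currents: capacitive peak present, ionic peaks missing
  sim0 <- simulate_sweep(protocol = quick_protocol(),
                         ionic = ionic_params(peak_ca = 0, peak_tail = 0),
                         noise = noise_model(seed = 4))
  pk0 <- locate_protocol_peaks(sim0$sweep)
  expect_false(is.na(pk0$peak_cap$index))
  expect_true(is.na(pk0$peak_ca$index))
  expect_true(is.na(pk0$peak_tail$index))
})

test_that("single-exponential fit recovers exact and noisy decays", {
  t <- seq(0, 100, by = 0.5)
  y <- 300 * exp(-t / 12) + 5
  fit <- fit_single_exponential(t, y)
  expect_true(fit$converged)
  expect_rel_equal(fit$params[["tau"]], 12, 1e-6)
  expect_rel_equal(fit$params[["a"]], 300, 1e-6)

  flat <- fit_single_exponential(t, rep(7, length(t)))
  expect_false(flat$converged)

  withr::with_seed(31, {
    t2 <- seq(0, 100, length.out = 2000)
    errs <- replicate(10, {
      y2 <- 300 * exp(-t2 / 12) + 5 + rnorm(2000, 0, 5)
      f <- fit_single_exponential(t2, y2)
      abs(f$params[["tau"]] - 12) / 12
    })
    expect_lt(stats::median(errs), 0.02)
  })
})

test_that("double-exponential fit recovers both constants, sorted", {
  t <- seq(0, 200, by = 0.2)
  y <- 400 * exp(-t / 3) + 100 * exp(-t / 40) - 20
  fit <- fit_double_exponential(t, y)
  expect_true(fit$converged)
  expect_rel_equal(fit$params[["tau1"]], 3, 1e-4)
  expect_rel_equal(fit$params[["tau2"]], 40, 1e-4)
  expect_lt(fit$params[["tau1"]], fit$params[["tau2"]])

  # non-identifiable truth (tau1 = tau2) is flagged degenerate
  y_eq <- 500 * exp(-t / 10) + 3
  f_eq <- fit_double_exponential(t, y_eq)
  if (f_eq$converged) expect_true(f_eq$degenerate)
})

test_that("fit residual never exceeds the truth's residual (no spurious optima)", {
  withr::with_seed(55, {
    t <- seq(0, 150, by = 0.3)
    for (trial in 1:20) {
      a <- runif(1, 100, 900); tau <- runif(1, 5, 40); c0 <- runif(1, -50, 50)
      y <- a * exp(-t / tau) + c0 + rnorm(length(t), 0, 4)
      fit <- fit_single_exponential(t, y)
      expect_true(fit$converged)
      rss_truth <- sum((y - (a * exp(-t / tau) + c0))^2)
      expect_lte(fit$rss, rss_truth * (1 + 1e-8))
    }
  })
})

test_that("AIC follows the least-squares form and selects parsimony", {
  expect_equal(compute_aic(100, 50, 5) - compute_aic(100, 50, 4), 2)
  expect_equal(compute_aic(50, 64, 4) - compute_aic(100, 64, 4), -64 * log(2))
  z <- compute_aic(0, 10, 4)
  expect_true(attr(z, "degenerate"))
  expect_lt(as.numeric(z), -1e299)
})

test_that("tail model selection matches the generating model", {
  t <- seq(0, 120, by = 0.1)
  withr::with_seed(77, {
    sel_double <- replicate(20, {
      y <- -600 * (0.65 * exp(-t / 4) + 0.35 * exp(-t / 40)) +
        rnorm(length(t), 0, sqrt(188))
      select_tail_model(t, y)$model
    })
    expect_gte(mean(sel_double == "double"), 0.95)
    sel_single <- replicate(20, {
      y <- -500 * exp(-t / 15) + rnorm(length(t), 0, 3)
      select_tail_model(t, y)$model
    })
    expect_gte(mean(sel_single == "single"), 0.9)
  })
  flat <- select_tail_model(t, rep(2, length(t)))
  expect_false(flat$converged)
})

test_that("baselines and areas follow their closed forms", {
  expect_equal(compute_baseline(c(1, 2, 10, 10, 10), 3), 10)
  ramp <- seq(1, 100)
  expect_equal(compute_baseline(ramp, 20), mean(81:100))
  expect_equal(compute_baseline(ramp, 100), mean(ramp))
  expect_error(compute_baseline(1:5, 6), "shorter")

  # triangle pulse, depth 100 pA over 10 ms: area = 500 pA*ms
  seg <- c(0, -50, -100, -50, 0)
  expect_equal(compute_area(seg, 2.5, 0), 500)
  expect_equal(compute_area(rep(-3, 50), 0.1, -3), 0)
  # trapezoid exact on piecewise-linear input
  x <- c(0, 2, 4, 4, 4, 1, -2)
  expect_equal(compute_area(x, 1, 5), sum((5 - x)[-1] + (5 - x)[-7]) / 2)
})

test_that("features recover the noiseless ground truth tightly", {
  sim <- simulate_sweep(noise = noise_model(0, 0))
  f <- extract_sweep_features(sim$sweep, fspec = filter_spec(L = 1))
  tr <- sim$truth
  expect_rel_equal(f$peak_ca_pA, tr$peak_ca, 1e-3)
  expect_rel_equal(f$peak_tail_pA, tr$peak_tail, 1e-3)
  expect_rel_equal(f$q_ca_pAms, tr$q_ca, 1e-3)
  expect_rel_equal(f$q_tail_pAms, tr$q_tail, 1e-3)
  expect_rel_equal(f$tau_ms, tr$tau, 0.01)
  expect_rel_equal(f$tau1_ms, tr$tau1, 0.01)
  expect_rel_equal(f$tau2_ms, tr$tau2, 0.01)

  # determinism: identical sweep in, identical features out
  f2 <- extract_sweep_features(sim$sweep, fspec = filter_spec(L = 1))
  expect_identical(f, f2)

  # zeroed ionic currents: near-zero charge, missing time constants
  sim0 <- simulate_sweep(ionic = ionic_params(peak_ca = 0, peak_tail = 0),
                         noise = noise_model(seed = 3))
  f0 <- extract_sweep_features(sim0$sweep)
  expect_lt(abs(f0$q_ca_pAms), 1500)   # consistent with pure noise
  expect_true(is.na(f0$tau_ms))
  expect_true(is.na(f0$tau1_ms))
})

test_that("recording-level extraction yields the canonical feature matrix", {
  cell <- generate_cell(protocol = quick_protocol(n_sweeps = 3L),
                        noise = noise_model(seed = 9))
  fm <- extract_recording_features(cell$recording)
  expect_identical(nrow(fm), 3L)
  core <- c("peak_ca_pA", "q_ca_pAms", "q_tail_pAms", "tau_ms", "tau1_ms", "tau2_ms")
  expect_true(all(core %in% names(fm)))
  expect_identical(length(core), 6L)   # 3 sweeps x 6 core features

  # a noiseless uniform recording gives identical rows
  cell0 <- generate_cell(protocol = quick_protocol(n_sweeps = 2L),
                         noise = noise_model(0, 0))
  fm0 <- extract_recording_features(cell0$recording, fspec = filter_spec(L = 2))
  expect_equal(fm0[1, -1], fm0[2, -1], ignore_attr = TRUE)
})
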