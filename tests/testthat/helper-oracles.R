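# Independent brute-force oracles and small synthetic builders shared
# across the suite.

# Brute-force peak finder: naive loops, same threshold semantics as the
# package detector (strict local maxima; height, MATLAB-style prominence,
# interpolated half-prominence width, then greedy minimum separation in
# descending height order).
bf_find_peaks <- function(x, cfg, polarity = "positive") {
  y <- if (polarity == "negative") -x else x
  n <- length(y)
  rows <- list()
  for (i in seq(2, n - 1)) {
    if (!(y[i] > y[i - 1] && y[i] > y[i + 1])) next
    if (y[i] < cfg$min_height) next
    jl <- i
    while (jl > 1 && y[jl - 1] <= y[i]) jl <- jl - 1
    jr <- i
    while (jr < n && y[jr + 1] <= y[i]) jr <- jr + 1
    base_l <- if (jl < i) min(y[jl:(i - 1)]) else y[i]
    base_r <- if (jr > i) min(y[(i + 1):jr]) else y[i]
    prom <- y[i] - max(base_l, base_r)
    if (prom < cfg$min_prominence) next
    ref <- y[i] - prom / 2
    xl <- jl
    k <- i
    while (k > jl && y[k - 1] > ref) k <- k - 1
    if (!(k == jl && y[k] > ref)) {
      xl <- (k - 1) + (ref - y[k - 1]) / (y[k] - y[k - 1])
    }
    xr <- jr
    k <- i
    while (k < jr && y[k + 1] > ref) k <- k + 1
    if (!(k == jr && y[k] > ref)) {
      xr <- k + (y[k] - ref) / (y[k] - y[k + 1])
    }
    if (xr - xl < cfg$min_width_samples) next
    rows[[length(rows) + 1]] <- c(index = i, height = y[i])
  }
  if (length(rows) == 0) return(integer(0))
  m <- do.call(rbind, rows)
  kept <- integer(0)
  for (j in order(m[, "height"], decreasing = TRUE)) {
    if (all(abs(m[j, "index"] - m[kept, "index"]) >= cfg$min_separation_samples)) {
      kept <- c(kept, j)
    }
  }
  sort(m[kept, "index"])
}

# Exhaustive permutation oracle for the two-sided rank-sum p-value
# (recursive enumeration of group-A index sets; mid-ranks throughout).
perm_ranksum_p <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a)
  n <- length(r)
  mu <- na * (n + 1) / 2
  obs <- abs(sum(r[seq_len(na)]) - mu)
  count <- 0L
  total <- 0L
  rec <- function(start, left, acc) {
    if (left == 0) {
      total <<- total + 1L
      if (abs(acc - mu) >= obs - 1e-9) count <<- count + 1L
      return(invisible())
    }
    for (i in start:(n - left + 1)) rec(i + 1, left - 1, acc + r[i])
  }
  rec(1, na, 0)
  count / total
}

# Small, fast protocol for tests that exercise the whole chain (half the
# canonical sweep duration; sampling keeps the Bessel cutoff below Nyquist).
quick_protocol <- function(n_sweeps = 4L, fs = 10e3, stim_freq = 2) {
  protocol_spec(t_hold = 50, n_sweeps = n_sweeps, stim_freq = stim_freq, fs = fs)
}

# A tiny recording for I/O tests (content is arbitrary but valid).
tiny_recording <- function(n_sweeps = 3L, n = 40L, seed = 99L) {
  withr::with_seed(seed, {
    sweeps <- lapply(seq_len(n_sweeps), function(i) {
      sweep_trace(current = rnorm(n, 0, 10),
                  voltage_cmd = rep(c(-80, 0), each = n / 2),
                  ts = 1e-3)
    })
    cell_recording(sweeps, cell_id = "tiny", regime_label = "uniform",
                   stimulation_frequency = 1)
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
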