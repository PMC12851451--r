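test_that("MAD noise estimator is consistent and trend-robust", {
  expect_equal(mad_noise_sigma(rep(5, 100)), 0)
  withr::with_seed(17, {
    x <- rnorm(1e5, 0, 188)
    expect_rel_equal(mad_noise_sigma(x), 188, 0.02)
    # a slow ramp barely perturbs the estimate (differencing detrends)
    x2 <- rnorm(1e5, 0, 188) + seq(0, 5000, length.out = 1e5)
    expect_rel_equal(mad_noise_sigma(x2), 188, 0.03)
  })
})

test_that("mean absolute error follows its definition and symmetry", {
  expect_equal(mean_absolute_error(1:5, 1:5), 0)
  expect_equal(mean_absolute_error(c(1, 2), c(2, 4)), 1.5)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(mean_absolute_error(a, b), mean_absolute_error(b, a))
  expect_error(mean_absolute_error(1:3, 1:4), "lengths differ")
})

test_that("normalized cross-correlation peaks at the true lag", {
  withr::with_seed(4, {
    a <- rnorm(200)
    self <- normalized_xcorr(a, a)
    expect_equal(self$value, 1, tolerance = 1e-12)
    expect_identical(self$lag, 0L)
    anti <- normalized_xcorr(a, -a)
    expect_equal(anti$value, -1, tolerance = 1e-12)
    expect_identical(anti$lag, 0L)
    b <- c(rep(0, 5), a[1:195])                 # b delayed by 5 samples
    shifted <- normalized_xcorr(a, b)
    expect_identical(shifted$lag, -5L)
    expect_gt(shifted$value, 0.95)
  })
  expect_error(normalized_xcorr(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("rank-sum test: exact values, invariances, approximations", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # fully separated 3 vs 3: two-sided exact p = 2 / C(6,3)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  # invariance under a common monotone transform
  a <- c(0.2, 1.5, 3.1, 4.4); b <- c(0.9, 2.2, 5.3)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value,
               wilcoxon_rank_sum(exp(a), exp(b))$p_value)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum matches the exhaustive permutation oracle (n <= 8)", {
  withr::with_seed(66, {
    for (trial in 1:30) {
      na <- sample(1:4, 1); nb <- sample(1:4, 1)
      vals <- if (trial %% 3 == 0) {
        sample(1:3, na + nb, replace = TRUE)      # heavy ties
      } else {
        rnorm(na + nb)
      }
      a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
      expect_equal(wilcoxon_rank_sum(a, b)$p_value, perm_ranksum_p(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("rank-sum agrees with the reference exact test on tie-free data", {
  withr::with_seed(91, {
    for (trial in 1:20) {
      a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1))
      expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                   stats::wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("significance stars map p-value bands with inclusive boundaries", {
  expect_identical(significance_stars(0.2), "ns")
  expect_identical(significance_stars(0.051), "ns")
  expect_identical(significance_stars(0.05), "*")
  expect_identical(significance_stars(0.03), "*")
  expect_identical(significance_stars(0.01), "**")
  expect_identical(significance_stars(0.001), "***")
  expect_identical(significance_stars(1e-4), "****")
  expect_identical(significance_stars(0), "****")
})

test_that("group comparison reports means, SEM and stars consistently", {
  df <- data.frame(
    regime_label = rep(c("alternant", "uniform"), c(4, 4)),
    v = c(10, 11, 12, 13, 30, 31, 32, 33)
  )
  cmp <- compare_groups(df)
  expect_equal(cmp$mean_alternant, 11.5)
  expect_equal(cmp$sem_alternant, stats::sd(c(10, 11, 12, 13)) / 2)
  expect_equal(cmp$p_value, 2 / choose(8, 4))
  expect_identical(cmp$stars, significance_stars(cmp$p_value))
  expect_error(compare_groups(df[df$regime_label == "uniform", ]), "2 groups")
})

test_that("agreement metrics behave on simulated vs noiseless trace pairs", {
  # the experimental recordings behind the reported agreement figures are
  # not deposited; the machinery is exercised on a synthetic pair
  sim <- simulate_sweep(protocol = quick_protocol(), noise = noise_model(seed = 12))
  sim0 <- simulate_sweep(protocol = quick_protocol(), noise = noise_model(0, 0))
  mae <- mean_absolute_error(sim$sweep$current, sim0$sweep$current)
  expect_gt(mae, 0)
  expect_rel_equal(mae, sqrt(188) * sqrt(2 / pi), 0.05)  # |N(0,s)| mean
  xc <- normalized_xcorr(sim$sweep$current, sim0$sweep$current)
  expect_identical(xc$lag, 0L)
  expect_gt(xc$value, 0.99)
  sig <- mad_noise_sigma(sim$sweep$current - sim0$sweep$current)
  expect_rel_equal(sig, sqrt(188), 0.05)
})
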