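# Noise estimation, model-agreement metrics, and the non-parametric group
# statistics used to compare uniform and alternant cells.

#' Robust noise estimate via the MAD of first differences
#'
#' Estimates the standard deviation of additive white noise on a slowly
#' varying signal: the first-difference series (scaled by 1/sqrt(2) to
#' undo the variance doubling of differencing) suppresses the signal
#' content, and the Gaussian-consistent MAD (constant 1.4826) of those
#' differences is robust to the residual transients.
#'
#' @param x Sample series (length >= 2).
#' @return Estimated noise SD, in the units of `x`; 0 for a constant
#'   series.
#' @export
mad_noise_sigma <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  stats::mad(diff(x) / sqrt(2))
}

#' Mean absolute error between two equal-length series
#'
#' @param a,b Numeric series of identical length.
#' @return `mean(abs(a - b))`.
#' @export
mean_absolute_error <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ", call. = FALSE)
  mean(abs(a - b))
}

#' Maximum normalized cross-correlation
#'
#' Zero-mean, unit-norm cross-correlation over all lags; the reported
#' value is the (signed) correlation at the lag of largest magnitude, so
#' a series against its negation reports -1 at lag 0.
#'
#' @param a,b Numeric series of identical length, each with nonzero
#'   variance.
#' @return A list `value` (in `[-1, 1]`) and `lag` (samples; positive
#'   means `b` is delayed relative to `a`).
#' @export
normalized_xcorr <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ", call. = FALSE)
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  na2 <- sum(a0^2); nb2 <- sum(b0^2)
  if (na2 == 0 || nb2 == 0) {
    stop("normalized cross-correlation undefined for zero-variance input",
         call. = FALSE)
  }
  # full cross-correlation r(k) = sum_t a0[t] b0[t - k], k = -(n-1)..(n-1)
  r <- stats::convolve(a0, b0, conj = TRUE, type = "open") / sqrt(na2 * nb2)
  lags <- seq.int(-(length(a) - 1L), length(a) - 1L)
  i <- which.max(abs(r))
  list(value = r[i], lag = lags[i])
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mid-ranks are used throughout, so ties are handled consistently. For
#' combined sample sizes up to `exact_max` (default 20) the p-value is
#' computed by exhaustive enumeration of all group assignments of the
#' pooled ranks (exact even with ties); beyond that, the normal
#' approximation with tie-corrected variance and continuity correction
#' is used.
#'
#' @param group_a,group_b Numeric vectors (each non-empty).
#' @param exact_max Largest combined n for exact enumeration.
#' @return A list: `statistic` (rank sum of `group_a`), `p_value`,
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(group_a, group_b, exact_max = 20L) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(group_a, group_b))
  n <- na + nb
  w <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (n <= exact_max) {
    sets <- utils::combn(n, na)
    w_all <- colSums(matrix(r[sets], nrow = na))
    p <- mean(abs(w_all - mu) >= abs(w - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (abs(w - mu) - 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal"
  }
  list(statistic = w, p_value = p, method = method)
}

#' Significance stars for a p-value
#'
#' Mapping: `p > 0.05` "ns", `p <= 0.05` "*", `p <= 0.01` "**",
#' `p <= 0.001` "***", `p <= 0.0001` "****" (boundaries inclusive).
#'
#' @param p A probability in `[0, 1]`.
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significance_stars <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p <= 1e-4) "****"
  else if (p <= 1e-3) "***"
  else if (p <= 1e-2) "**"
  else if (p <= 0.05) "*"
  else "ns"
}

#' Standard error of the mean
#' @param x Numeric vector (`NA` dropped).
#' @return `sd(x)/sqrt(n)`.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  stats::sd(x) / sqrt(length(x))
}

#' Compare feature values between two regimes
#'
#' For every value column: group means with SEM, the two-sided Wilcoxon
#' rank-sum p-value, and its star label. Values with `NA` are dropped
#' per column.
#'
#' @param df A data.frame holding the value columns and a grouping
#'   column.
#' @param group_col Name of the grouping column (exactly two levels must
#'   be present).
#' @param value_cols Value columns to compare (default: all numeric
#'   columns except the group).
#' @return A data.frame with one row per feature: `feature`,
#'   `mean_<level>`, `sem_<level>` for both levels, `p_value`, `stars`,
#'   `n_<level>` counts.
#' @export
compare_groups <- function(df, group_col = "regime_label", value_cols = NULL) {
  stopifnot(is.data.frame(df), group_col %in% names(df))
  g <- as.character(df[[group_col]])
  lev <- sort(unique(g))
  if (length(lev) != 2L) {
    stop(sprintf("need exactly 2 groups in '%s', found %d", group_col,
                 length(lev)), call. = FALSE)
  }
  if (is.null(value_cols)) {
    value_cols <- names(df)[vapply(df, is.numeric, logical(1))]
    value_cols <- setdiff(value_cols, group_col)
  }
  rows <- lapply(value_cols, function(cn) {
    a <- df[[cn]][g == lev[1L]]
    b <- df[[cn]][g == lev[2L]]
    wt <- wilcoxon_rank_sum(a, b)
    out <- data.frame(
      feature = cn,
      m1 = mean(a, na.rm = TRUE), s1 = sem(a),
      m2 = mean(b, na.rm = TRUE), s2 = sem(b),
      n1 = sum(!is.na(a)), n2 = sum(!is.na(b)),
      p_value = wt$p_value, stars = significance_stars(wt$p_value)
    )
    names(out) <- c("feature",
                    paste0(c("mean_", "sem_"), lev[1L]),
                    paste0(c("mean_", "sem_"), lev[2L]),
                    paste0("n_", lev),
                    "p_value", "stars")
    out
  })
  do.call(rbind, rows)
}
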