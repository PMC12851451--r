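# The alternation index: successive feature differences and the
# normalized mean-to-max ratio of their squares.

#' Successive differences of a per-sweep feature series
#'
#' `D(t) = m(t) - m(t-1)` for `t = 2..N`. A difference is only defined
#' when both neighbours are present; missing entries yield `NA`
#' differences, which downstream statistics drop pairwise.
#'
#' @param m Feature series (length >= 2).
#' @return Numeric vector of length `length(m) - 1`.
#' @export
successive_differences <- function(m) {
  if (length(m) < 2L) stop("need at least 2 values", call. = FALSE)
  diff(m)
}

#' Alternation index of a feature series
#'
#' `CIdx = mean(D^2) / max(D^2)`, where `D` are the successive
#' differences of the series. The index lies in `[0, 1]`: a perfect
#' square-wave alternation (all squared differences equal) scores exactly
#' 1, irregular or isolated jumps score low. It is invariant to shifting
#' and rescaling the series, but not to permuting it -- order is the
#' point. A perfectly constant series carries no alternation evidence:
#' by convention it scores 0 and is flagged `degenerate`, as is any
#' series with fewer than 2 usable differences.
#'
#' @param m Feature series (missing values allowed; differences are
#'   formed between adjacent available sweeps).
#' @param feature_name Optional label carried into the result.
#' @return An `alternation_result` list: `feature_name`, `cidx`,
#'   `n_used` (usable differences + 1), `degenerate`.
#' @export
alternation_index <- function(m, feature_name = NA_character_) {
  d <- successive_differences(m)
  d <- d[!is.na(d)]
  res <- function(cidx, degenerate) {
    structure(list(feature_name = feature_name, cidx = cidx,
                   n_used = length(d) + 1L, degenerate = degenerate),
              class = "alternation_result")
  }
  if (length(d) < 2L) return(res(NA_real_, TRUE))
  d2 <- d^2
  mx <- max(d2)
  if (mx == 0) return(res(0, TRUE))
  res(mean(d2) / mx, FALSE)
}

#' @export
print.alternation_result <- function(x, ...) {
  cat(sprintf("<alternation_result> %s: CIdx = %s (n = %d%s)\n",
              if (is.na(x$feature_name)) "series" else x$feature_name,
              format(x$cidx, digits = 4), x$n_used,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Alternation index of every feature column
#'
#' Applies [alternation_index()] to each feature column of a per-sweep
#' feature matrix.
#'
#' @param matrix A feature matrix from [extract_recording_features()]
#'   (or any data.frame of per-sweep feature columns; a `sweep` column is
#'   ignored).
#' @return A data.frame with one row per feature: `feature`, `cidx`,
#'   `n_used`, `degenerate`.
#' @export
index_over_features <- function(matrix) {
  stopifnot(is.data.frame(matrix), nrow(matrix) >= 2L)
  cols <- setdiff(names(matrix), "sweep")
  rows <- lapply(cols, function(cn) {
    r <- alternation_index(matrix[[cn]], feature_name = cn)
    data.frame(feature = cn, cidx = r$cidx, n_used = r$n_used,
               degenerate = r$degenerate)
  })
  do.call(rbind, rows)
}
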