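# Quantile subsampling for noise reduction.
#
# The raw node-statistic sample is sorted ascending by absolute value and n
# points are extracted at the mid-quantile ranks i' = round(d*(2i-1)/2)
# with step d = N/n, i.e. at empirical cumulative positions
# P_c = (2i-1)/(2n) = 0.05, 0.15, ..., 0.95 for n = 10. Averaging over
# ranks in this way discards the noise-dominated extremes of the empirical
# CDF while preserving its shape.

#' Quantile subsample of a node-statistic sample
#'
#' Sorts the sample ascending by absolute value (stable sort: ties keep
#' input order) and extracts the values at mid-quantile ranks
#' `i' = round_half_up(d * (2i - 1) / 2)` with step `d = N/n` for
#' `i = 1..n`, clamped to `[1, N]`. The corresponding empirical cumulative
#' positions `i'/N` are the mid-quantiles `0.05, 0.15, ..., 0.95` when
#' `n = 10` and `N` is a multiple of `n`; `n = N` is the identity
#' selection.
#'
#' @param x Numeric sample of size `N`.
#' @param n Number of points to extract, `1 <= n <= N`.
#' @return List with `values` (the extracted points, a non-decreasing
#'   subsequence of the sorted sample) and `scheme` (list with `n`, `N`,
#'   step `d`, 1-based `indices`, and cumulative `positions = indices/N`).
#' @examples
#' subsample(seq_len(100), 10)$scheme$indices  # 5, 15, ..., 95
#' @export
subsample <- function(x, n) {
  if (!is.numeric(x) || length(x) == 0) {
    rpl_stop("rplnet_param_error", "`x` must be a nonempty numeric sample")
  }
  N <- length(x)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n > N) {
    rpl_stop("rplnet_subsample_error",
             "`n` must satisfy 1 <= n <= N (got n = %s, N = %d)", toString(n), N)
  }
  n <- as.integer(n)
  sorted <- x[order(abs(x))]  # order() is a stable sort
  d <- N / n
  idx <- floor(d * (2 * seq_len(n) - 1) / 2 + 0.5)  # round half-up
  idx <- pmin(pmax(idx, 1), N)
  list(values = sorted[idx],
       scheme = list(n = n, N = N, d = d, indices = as.integer(idx),
                     positions = idx / N))
}
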