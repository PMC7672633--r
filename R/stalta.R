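#' Short-term over long-term average (STA/LTA)
#'
#' The classical trigger statistic of observational seismology, shared by
#' the seismic amplitude trigger and the D-call ratio smoother: at index
#' `i` it is the mean of the last `sta_len` values ending at `i` divided by
#' the mean of the last `lta_len` values ending at `i`.  During warm-up
#' (fewer than `lta_len` values available) each average uses the available
#' prefix, so no samples are dropped.  Indices where the long-term mean is
#' zero (signal absent) yield 0.
#'
#' Because the long-term window contains the short-term one, the statistic
#' is bounded above by `lta_len / sta_len` and equals 1 on any constant
#' positive series.
#'
#' @param series Non-negative numeric series (e.g. `|x|` or a ratio curve).
#' @param sta_len Short-term window length, in samples of `series`.
#' @param lta_len Long-term window length; must exceed `sta_len`.
#' @return Numeric vector of the same length as `series`.
#' @examples
#' stalta(rep(2, 30), 5, 15)        # all 1
#' stalta(c(rep(0, 9), 1), 1, 10)   # last value 10
#' @export
stalta <- function(series, sta_len, lta_len) {
  if (length(series) == 0) stop("`series` must be non-empty")
  if (sta_len < 1 || lta_len <= sta_len) {
    stop("need 1 <= sta_len < lta_len")
  }
  if (any(series < 0)) stop("`series` must be non-negative")
  n <- length(series)
  cs <- cumsum(series)
  i <- seq_len(n)
  run_mean <- function(k) {
    len <- pmin(i, k)
    s <- cs
    if (n > k) {
      tail_i <- (k + 1):n
      s[tail_i] <- cs[tail_i] - cs[tail_i - k]
    }
    s / len
  }
  sta <- run_mean(sta_len)
  lta <- run_mean(lta_len)
  out <- numeric(n)
  nz <- lta > 0
  out[nz] <- sta[nz] / lta[nz]
  out
}
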