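## Rank-1 singular spectrum analysis (SSA) smoothing.
##
## The fitting objective weights residuals by a per-subject, per-channel
## variance estimated from the raw data: the series is smoothed by SSA
## with only the leading eigentriple retained, and the variance of the
## deviations from that trend is taken as the expected residual variance
## of any model fit.

#' Rank-1 SSA trend of a series
#'
#' Embeds the series in a Hankel trajectory matrix of window length
#' `window`, takes the leading singular triple of its SVD, and
#' reconstructs a series of the original length by anti-diagonal
#' averaging.  A constant series, or any series with rank-1 Hankel
#' structure (e.g. a geometric progression), is reproduced exactly.
#'
#' @param x numeric vector (length >= 4) or a [sampled_series()].
#' @param window SSA window length `L`, between 2 and `length(x) - 1`;
#'   defaults to `floor(n/2)`, the standard choice for trend extraction.
#' @return the trend, in the same form as the input.
#' @export
ssa_trend <- function(x, window = NULL) {
  series <- NULL
  if (is.data.frame(x)) {
    series <- as_series(x)
    x <- series$value
  }
  n <- length(x)
  if (n < 4L) stop("series must have at least 4 samples")
  if (is.null(window)) window <- floor(n / 2)
  if (window < 2L || window > n - 1L)
    stop("'window' must lie in [2, n-1]")
  L <- as.integer(window)
  K <- n - L + 1L
  H <- matrix(0, L, K)
  for (j in seq_len(K)) H[, j] <- x[j:(j + L - 1L)]
  sv <- svd(H, nu = 1L, nv = 1L)
  R1 <- sv$d[1L] * tcrossprod(sv$u[, 1L], sv$v[, 1L])
  # anti-diagonal (Hankel) averaging back to a series
  trend <- numeric(n)
  count <- numeric(n)
  for (j in seq_len(K)) {
    idx <- j:(j + L - 1L)
    trend[idx] <- trend[idx] + R1[, j]
    count[idx] <- count[idx] + 1
  }
  trend <- trend / count
  if (!is.null(series)) sampled_series(series$time, trend) else trend
}

#' Residual variance of a series about its SSA trend
#'
#' Returns the plain mean of squared deviations of the data from the
#' rank-1 SSA trend — the "variance per time point" used to weight the
#' fitting objective, one scalar per (protocol, channel) pair.  A
#' strictly positive floor of `(floor_frac * mean(x))^2` is applied so
#' that noiseless (e.g. synthetic) channels do not receive infinite
#' weight.
#'
#' @inheritParams ssa_trend
#' @param floor_frac floor on the residual standard deviation, as a
#'   fraction of the channel mean (default 0.01).
#' @return a list with elements `sigma2` (the variance estimate) and
#'   `trend` (same form as the input).
#' @export
estimate_variance <- function(x, window = NULL, floor_frac = 0.01) {
  vals <- if (is.data.frame(x)) as_series(x)$value else x
  trend <- ssa_trend(x, window = window)
  tvals <- if (is.data.frame(trend)) trend$value else trend
  sigma2 <- mean((vals - tvals)^2)
  floor_val <- (floor_frac * mean(vals))^2
  if (sd(vals) == 0)
    warning("series is constant; variance set to the floor")
  list(sigma2 = max(sigma2, floor_val), trend = trend)
}
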