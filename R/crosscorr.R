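#' Normalized cross-correlation over the full lag range
#'
#' Computes the raw cross-correlation `z[k] = sum_i x[i] * y[i - k]` for
#' every lag `k` from `-(n - 1)` to `n - 1`, including lags where the two
#' signals only partially overlap, and scales it by `sqrt(sum(x^2) *
#' sum(y^2))` (global energy) so the coefficients fall in [-1, 1] and are
#' independent of signal amplitude. With this formula, if `y` is a delayed
#' copy of `x` (`y[i] = x[i - d]`, `y` lagging by `d` samples) the peak
#' occurs at `k = -d`: negative peak lags mean `y` trails `x`.
#'
#' Signals are mean-centred over the analysis window by default (a common
#' offset would otherwise dominate the peak); disable with
#' `center = FALSE`. A per-lag normalization (dividing each lag by the
#' energies of the overlapping segments only) is available via
#' `scale = "per_lag"`; coefficients at lags whose overlap fraction falls
#' below `min_overlap` are flagged.
#'
#' @param x,y Equal-length numeric time courses.
#' @param sampling_rate_hz Sampling rate used to express lags in ms.
#' @param center Mean-centre both signals first (default `TRUE`).
#' @param scale `"global"` (default) or `"per_lag"` normalization.
#' @param min_overlap Minimum overlap fraction for a lag to be considered
#'   reliable (flag only; all lags are returned).
#' @return An `xcorr_result` tibble: `lag` (samples), `lag_ms`,
#'   `coefficient`, `overlap`, `reliable`. Supports [autoplot()].
#' @examples
#' x <- sin(seq(0, 4 * pi, length.out = 100))
#' r <- normalized_xcorr(x, x, sampling_rate_hz = 250)
#' peak_lag(r)   # 0 ms
#' @export
normalized_xcorr <- function(x, y, sampling_rate_hz = 250,
                             center = TRUE,
                             scale = c("global", "per_lag"),
                             min_overlap = 0.5) {
  scale <- match.arg(scale)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 2) abort("Signals must have at least 2 samples.")
  if (anyNA(x) || anyNA(y)) abort("Signals must not contain missing values.")
  if (center) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Constant signal: normalization undefined.")
  }
  lags <- -(n - 1):(n - 1)
  # convolve(x, y, type = "open") reverses y internally, i.e. it returns
  # exactly z[j] = sum_i x[i] y[i - (j - n)], the lag-(j - n)
  # cross-correlation, ordered from k = -(n-1) to k = n-1
  z <- convolve(x, y, type = "open")
  overlap <- (n - abs(lags)) / n
  if (scale == "global") {
    coef <- z / sqrt(sum(x^2) * sum(y^2))
  } else {
    seg_x <- vapply(lags, function(k) {
      i <- pmax(1, 1 + k):pmin(n, n + k)
      sum(x[i]^2)
    }, numeric(1))
    seg_y <- vapply(lags, function(k) {
      i <- pmax(1, 1 - k):pmin(n, n - k)
      sum(y[i]^2)
    }, numeric(1))
    denom <- sqrt(seg_x * seg_y)
    coef <- ifelse(denom > 0, z / denom, NA_real_)
  }
  out <- tibble::tibble(
    lag = lags,
    lag_ms = lags * 1000 / sampling_rate_hz,
    coefficient = coef,
    overlap = overlap,
    reliable = overlap >= min_overlap
  )
  structure(out, class = c("xcorr_result", class(out)),
            sampling_rate_hz = sampling_rate_hz, scale = scale)
}

#' Peak lag of a cross-correlation
#'
#' Returns the lag (ms) at which the cross-correlation coefficient is
#' maximal. Exact ties are broken toward the smallest absolute lag, then
#' toward the negative lag, so the result is deterministic.
#'
#' @param result An [normalized_xcorr()] result.
#' @param restrict_reliable Only consider lags whose overlap fraction met
#'   `min_overlap` (default `TRUE`).
#' @return Peak lag in ms (length-1 numeric).
#' @export
peak_lag <- function(result, restrict_reliable = TRUE) {
  stopifnot(inherits(result, "xcorr_result"))
  d <- if (restrict_reliable) result[result$reliable, ] else result
  d <- d[is.finite(d$coefficient), ]
  if (!nrow(d)) abort("No finite cross-correlation coefficients available.")
  best <- d$coefficient == max(d$coefficient)
  cand <- d[best, ]
  cand <- cand[order(abs(cand$lag), cand$lag), ]
  cand$lag_ms[1]
}

#' Group test of cross-correlation peak lags against zero
#'
#' One-sample t test (with Cohen's d) of per-participant peak lags against
#' zero lag: a non-significant result is consistent with synchronous
#' signals, a significant one with a systematic lead or lag.
#'
#' @param peak_lags_ms Numeric vector, one peak lag (ms) per participant.
#' @return One-row tibble from [t_test_d()].
#' @export
zero_lag_test <- function(peak_lags_ms) {
  t_test_d(peak_lags_ms)
}

#' Express a time course as a percentage of its peak magnitude
#'
#' Divides a course by the maximum of its absolute value and multiplies by
#' 100, so its extreme becomes +100 or -100 while the sign of every point
#' is preserved. Used to overlay visual and motor reselection courses with
#' different native amplitudes.
#'
#' @param course Numeric vector with at least one nonzero value.
#' @return Rescaled numeric vector.
#' @export
normalize_to_peak <- function(course) {
  if (anyNA(course)) abort("`course` must not contain missing values.")
  peak <- max(abs(course))
  if (peak == 0) abort("All-zero course cannot be normalized to its peak.")
  100 * course / peak
}
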