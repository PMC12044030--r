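#' Generalized extreme studentized deviate (ESD) outlier rejection
#'
#' Rosner's generalized ESD procedure for detecting up to `max_outliers`
#' outliers in approximately normal data, used here to flag high-variance
#' trials before spectral analysis. The procedure repeatedly removes the
#' most extreme studentized point and compares each extreme-deviate
#' statistic R_i against its critical value lambda_i; the number of
#' outliers is the largest i for which R_i exceeds lambda_i (so an inner
#' non-significant step cannot mask a more extreme later one).
#'
#' @param trial_scores Per-trial summary scores (e.g. log variance);
#'   finite numeric vector.
#' @param max_outliers Maximum number of outliers tested (must be below
#'   half the number of scores). Default: 10% of trials, at least 1.
#' @param alpha Significance level of the outlier test.
#' @return An `esd_result`: `outliers` (integer indices into
#'   `trial_scores`, possibly empty), `n_outliers`, and `steps`, a tibble
#'   with one row per tested step (`i`, `index`, `score`, `R`, `lambda`,
#'   `significant`). Supports [tidy()].
#' @examples
#' x <- c(rnorm(99), 10)
#' esd_reject(x)$outliers
#' @export
esd_reject <- function(trial_scores, max_outliers = NULL, alpha = 0.05) {
  x <- trial_scores
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort("`trial_scores` must be finite numeric values.")
  }
  n <- length(x)
  if (n < 5) abort("Need at least 5 scores for ESD rejection.")
  if (is.null(max_outliers)) max_outliers <- max(1L, floor(n * 0.1))
  if (max_outliers >= n / 2) {
    abort("`max_outliers` must be smaller than half the number of scores.")
  }
  remaining <- seq_len(n)
  steps <- vector("list", max_outliers)
  for (i in seq_len(max_outliers)) {
    xi <- x[remaining]
    s <- sd(xi)
    if (s == 0) {
      steps <- steps[seq_len(i - 1)]
      break
    }
    dev <- abs(xi - mean(xi))
    j <- which.max(dev)
    r_i <- dev[j] / s
    ni <- length(xi)
    p <- 1 - alpha / (2 * ni)
    tcrit <- qt(p, ni - 2)
    lambda_i <- (ni - 1) * tcrit / sqrt((ni - 2 + tcrit^2) * ni)
    steps[[i]] <- tibble::tibble(
      i = i, index = remaining[j], score = xi[j],
      R = r_i, lambda = lambda_i, significant = r_i > lambda_i
    )
    remaining <- remaining[-j]
  }
  steps <- dplyr::bind_rows(steps)
  n_out <- if (nrow(steps) && any(steps$significant)) {
    max(steps$i[steps$significant])
  } else 0L
  structure(
    list(outliers = if (n_out > 0) sort(steps$index[seq_len(n_out)])
         else integer(0),
         n_outliers = as.integer(n_out), steps = steps,
         alpha = alpha, n = n),
    class = "esd_result"
  )
}

#' @export
print.esd_result <- function(x, ...) {
  cat("<esd_result> ", x$n_outliers, " outlier(s) among ", x$n,
      " scores (alpha = ", x$alpha, ")\n", sep = "")
  if (x$n_outliers > 0) cat("  indices:", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}

#' Per-trial variance scores for ESD trial rejection
#'
#' Summarises each trial of an [epoch_array()] by the log of its total
#' signal variance across channels, the score on which [esd_reject()]
#' operates.
#'
#' @param epochs An [epoch_array()].
#' @return Tibble: `participant`, `trial`, `score`.
#' @export
trial_variance_scores <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_array"))
  purrr::map_dfr(seq_along(epochs$data), function(i) {
    arr <- epochs$data[[i]]
    v <- apply(arr, 1, function(tr) mean(apply(tr, 1, var)))
    tibble::tibble(participant = epochs$participants[i],
                   trial = epochs$trials[[i]], score = log(v))
  })
}
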