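#' Tidy a circular mixture fit
#'
#' @param x A `mixture_fit` from [fit_mixture()].
#' @param ... Unused.
#' @return One-row tibble with the proportions, `kappa`, `sd_deg`,
#'   `log_likelihood`, `n`, `boundary`.
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble::tibble(
    p_target = x$p_target, p_nontarget = x$p_nontarget,
    p_guess = x$p_guess, kappa = x$kappa, sd_deg = x$sd_deg,
    log_likelihood = x$log_likelihood, n = x$n, boundary = x$boundary
  )
}

#' @rdname tidy.mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(log_likelihood = x$log_likelihood, n = x$n,
                 boundary = x$boundary)
}

#' Tidy a cluster permutation test result
#'
#' @param x A `cluster_result` from [cluster_permutation_test()].
#' @param ... Unused.
#' @return Tibble of clusters (index and axis ranges, mass, p), zero rows
#'   when no cluster survived the threshold.
#' @export
tidy.cluster_result <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x$clusters), -dplyr::any_of("indices"))
}

#' @rdname tidy.cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$p < 0.05),
    min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_,
    n_permutations = x$n_permutations,
    method = x$method,
    cluster_alpha = x$cluster_alpha
  )
}

#' Tidy an ESD outlier-rejection result
#'
#' @param x An `esd_result` from [esd_reject()].
#' @param ... Unused.
#' @return The per-step tibble with an `outlier` column marking the
#'   finally flagged points.
#' @export
tidy.esd_result <- function(x, ...) {
  dplyr::mutate(x$steps, outlier = .data$i <= x$n_outliers)
}

#' @rdname tidy.esd_result
#' @export
glance.esd_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_outliers = x$n_outliers, alpha = x$alpha)
}
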