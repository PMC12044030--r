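#' Cluster-based sign-flip permutation test against zero
#'
#' Nonparametric family-wise inference for participant-resolved time
#' courses (participants x time) or time-frequency maps (participants x
#' frequency x time). At each point a one-sample t statistic against zero
#' is computed and thresholded at the two-sided critical value for
#' `cluster_alpha`; contiguous supra-threshold points (1-D runs, or
#' 4-neighbourhood connected components in 2-D) of common sign form
#' clusters whose mass is the sum of their t values. The null distribution
#' of the maximum absolute cluster mass is built by randomly flipping the
#' sign of each participant's whole dataset (exchangeable under the null of
#' zero mean), and each observed cluster's p-value is the proportion of the
#' null at or above its absolute mass, with the +1 small-sample correction
#' for random permutation sets.
#'
#' When all `2^n` sign patterns number no more than `n_perm`, the test
#' enumerates them exhaustively and p-values are exact proportions over the
#' full enumeration (the identity pattern included, so p is never below
#' `1 / 2^n`).
#'
#' @param data Numeric matrix participants x time, or 3-D array
#'   participants x frequency x time. No missing values.
#' @param n_perm Number of random sign-flip permutations (default 1024).
#' @param cluster_alpha Alpha of the two-sided cluster-forming threshold.
#' @param sides Which clusters to report: `"both"`, `"positive"`, or
#'   `"negative"`. The null maximum is always taken over both signs.
#' @param time,freq Optional axis values (ms, Hz) used to label clusters.
#' @param seed Optional integer seed for the permutation RNG.
#' @return A `cluster_result`: tibble of clusters (id, `sign`, index
#'   ranges, axis ranges when provided, `mass`, `p`), the threshold,
#'   the effective number of permutations, and `method`
#'   (`"exhaustive"` or `"random"`). Supports [tidy()] and [glance()].
#' @examples
#' x <- matrix(rnorm(20 * 50), 20) + rep(c(rep(0, 20), rep(1, 10), rep(0, 20)),
#'                                       each = 20)
#' cluster_permutation_test(x, n_perm = 256, seed = 1)
#' @export
cluster_permutation_test <- function(data, n_perm = 1024,
                                     cluster_alpha = 0.05,
                                     sides = c("both", "positive", "negative"),
                                     time = NULL, freq = NULL, seed = NULL) {
  sides <- match.arg(sides)
  dims <- dim(data)
  if (is.null(dims) || !(length(dims) %in% 2:3)) {
    abort("`data` must be participants x time or participants x freq x time.")
  }
  is_2d <- length(dims) == 3
  n <- dims[1]
  if (n < 2) abort("Need at least 2 participants.")
  X <- if (is_2d) matrix(data, nrow = n) else data
  if (anyNA(X)) abort("`data` must not contain missing values.")
  k <- ncol(X)

  m <- colMeans(X)
  ss <- colSums(X^2)
  v <- (ss - n * m^2) / (n - 1)
  v[v < 0] <- 0
  if (any(v == 0 & abs(m) > 1e-12)) {
    abort("Zero-variance data with nonzero mean cannot be tested.")
  }
  t_obs <- ifelse(v == 0, 0, m / sqrt(v / n))
  thr <- qt(1 - cluster_alpha / 2, df = n - 1)

  clusters <- if (is_2d) {
    observed_clusters_2d(t_obs, dims[2], dims[3], thr)
  } else {
    observed_clusters_1d(t_obs, thr)
  }

  exhaustive <- n <= 30 && 2^n <= n_perm
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    storage.mode(signs) <- "double"
  } else {
    signs <- with_seed_if(seed, {
      matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), nrow = n_perm)
    })
  }
  null_max <- perm_null_max(X, signs, ss, n, thr,
                            if (is_2d) dims[2:3] else NULL)

  if (nrow(clusters)) {
    clusters$p <- vapply(clusters$mass, function(mm) {
      # tolerance so the identity permutation's mass, recomputed through
      # the permutation path, always counts as >= the observed mass
      cut <- abs(mm) - 1e-8 * max(1, abs(mm))
      if (exhaustive) mean(null_max >= cut)
      else (1 + sum(null_max >= cut)) / (1 + nrow(signs))
    }, numeric(1))
    if (sides == "positive") clusters <- clusters[clusters$sign > 0, ]
    if (sides == "negative") clusters <- clusters[clusters$sign < 0, ]
    clusters <- clusters[order(clusters$p, -abs(clusters$mass)), ]
    clusters$cluster <- seq_len(nrow(clusters))
    clusters <- dplyr::relocate(clusters, "cluster")
  } else {
    clusters$p <- numeric(0)
  }
  clusters <- label_cluster_axes(clusters, is_2d, time, freq)

  structure(
    list(clusters = clusters, threshold_t = thr, df = n - 1,
         n_permutations = nrow(signs),
         method = if (exhaustive) "exhaustive" else "random",
         cluster_alpha = cluster_alpha, sides = sides,
         null_max = null_max, t_map = t_obs,
         dims = dims, time = time, freq = freq),
    class = "cluster_result"
  )
}

# Null distribution of the maximum absolute cluster mass, chunked over
# permutations to bound memory. `ss` (per-point sums of squares) is
# invariant under sign flips, so only the mean changes per permutation.
perm_null_max <- function(X, signs, ss, n, thr, grid = NULL) {
  n_perm <- nrow(signs)
  out <- numeric(n_perm)
  chunk <- max(1, floor(2e6 / ncol(X)))
  for (lo in seq(1, n_perm, by = chunk)) {
    hi <- min(lo + chunk - 1, n_perm)
    M <- (signs[lo:hi, , drop = FALSE] %*% X) / n
    V <- (rep(1, hi - lo + 1) %o% ss - n * M^2) / (n - 1)
    V[V < 1e-300] <- 1e-300
    Tm <- M / sqrt(V / n)
    Tm[!is.finite(Tm)] <- 0
    out[lo:hi] <- if (is.null(grid)) {
      perm_max_mass_1d(Tm, thr)
    } else {
      perm_max_mass_2d(Tm, grid[1], grid[2], thr)
    }
  }
  out
}

observed_clusters_1d <- function(t_obs, thr) {
  s <- ifelse(t_obs > thr, 1L, ifelse(t_obs < -thr, -1L, 0L))
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0
  tibble::tibble(
    sign = r$values[keep],
    start = starts[keep],
    end = ends[keep],
    n_points = r$lengths[keep],
    mass = purrr::map2_dbl(starts[keep], ends[keep],
                           ~ sum(t_obs[.x:.y]))
  )
}

observed_clusters_2d <- function(t_obs, nf, nt, thr) {
  s <- ifelse(t_obs > thr, 1L, ifelse(t_obs < -thr, -1L, 0L))
  lab <- label_components_2d(as.integer(s), nf, nt)
  n_lab <- attr(lab, "n_labels")
  if (n_lab == 0) {
    return(tibble::tibble(sign = integer(), start = integer(),
                          end = integer(), n_points = integer(),
                          mass = double(), indices = list(),
                          freq_start = integer(), freq_end = integer()))
  }
  purrr::map_dfr(seq_len(n_lab), function(l) {
    idx <- which(lab == l)
    rows <- (idx - 1) %% nf + 1
    cols <- (idx - 1) %/% nf + 1
    tibble::tibble(
      sign = s[idx[1]],
      start = min(cols), end = max(cols),
      n_points = length(idx),
      mass = sum(t_obs[idx]),
      indices = list(idx),
      freq_start = min(rows), freq_end = max(rows)
    )
  })
}

label_cluster_axes <- function(clusters, is_2d, time, freq) {
  if (!is.null(time) && nrow(clusters)) {
    clusters$start_ms <- time[clusters$start]
    clusters$end_ms <- time[clusters$end]
  }
  if (is_2d && !is.null(freq) && nrow(clusters)) {
    clusters$freq_lo_hz <- freq[clusters$freq_start]
    clusters$freq_hi_hz <- freq[clusters$freq_end]
  }
  clusters
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", x$method, " sign-flip test, ",
      x$n_permutations, " permutations, |t| > ",
      round(x$threshold_t, 3), " (df = ", x$df, ")\n", sep = "")
  if (nrow(x$clusters)) {
    print(dplyr::select(x$clusters, -dplyr::any_of("indices")), ...)
  } else {
    cat("  no supra-threshold clusters\n")
  }
  invisible(x)
}

#' Paired cluster-based permutation test
#'
#' Tests two matched participant x time (or x frequency x time) datasets
#' for a difference by applying [cluster_permutation_test()] to `a - b`
#' (sign flips of within-participant differences are the exact permutation
#' scheme for a paired design).
#'
#' @param a,b Matched numeric arrays of identical dimensions.
#' @inheritParams cluster_permutation_test
#' @param ... Passed to [cluster_permutation_test()].
#' @return A `cluster_result`.
#' @export
paired_cluster_test <- function(a, b, ...) {
  if (!identical(dim(a), dim(b))) {
    abort("`a` and `b` must have identical dimensions.")
  }
  cluster_permutation_test(a - b, ...)
}

#' One-sample and paired t test with Cohen's d
#'
#' Standard t statistics with the effect size the field reports: for a
#' one-sample test, d = mean / sd; for a paired test (`y` supplied) the
#' test is run on the within-participant differences `x - y` and d is
#' computed on those difference scores.
#'
#' @param x Numeric vector (or first condition of a pair).
#' @param y Optional matched second condition.
#' @param mu Null value (default 0).
#' @return One-row tibble: `estimate`, `t`, `df`, `p_value`, `cohens_d`,
#'   `n`, and `zero_variance` (if `TRUE`, the data had no spread and `t`
#'   is signed infinity, flagged rather than dropped).
#' @examples
#' t_test_d(c(1.2, 0.8, 1.1), mu = 0)
#' @export
t_test_d <- function(x, y = NULL, mu = 0) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) abort("`x` and `y` must be matched (equal length).")
    x - y
  }
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) abort("Need at least 2 observations.")
  est <- mean(d)
  s <- sd(d)
  if (s == 0) {
    tval <- if (est == mu) 0 else sign(est - mu) * Inf
    return(tibble::tibble(estimate = est, t = tval, df = n - 1,
                          p_value = if (est == mu) 1 else 0,
                          cohens_d = tval, n = n, zero_variance = TRUE))
  }
  tval <- (est - mu) / (s / sqrt(n))
  tibble::tibble(
    estimate = est, t = tval, df = n - 1,
    p_value = 2 * pt(-abs(tval), n - 1),
    cohens_d = (est - mu) / s, n = n, zero_variance = FALSE
  )
}
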