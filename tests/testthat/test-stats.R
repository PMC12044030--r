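test_that("cluster test handles nulls, constructed effects, and zero data", {
  # exact zeros: no clusters, no error
  res0 <- cluster_permutation_test(matrix(0, 8, 12), n_perm = 64, seed = 1)
  expect_equal(nrow(res0$clusters), 0)

  # constant nonzero columns are rejected
  expect_error(cluster_permutation_test(matrix(1, 8, 12), n_perm = 64),
               "Zero-variance")

  # a large planted offset produces one significant covering cluster
  withr::with_seed(2, {
    x <- matrix(rnorm(20 * 30), 20) + 3
    res <- cluster_permutation_test(x, n_perm = 256, seed = 3)
  })
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$start, 1)
  expect_equal(res$clusters$end, 30)
  expect_lt(res$clusters$p, 0.01)
  expect_equal(res$clusters$sign, 1)
})

test_that("p-values match exhaustive enumeration on small cohorts", {
  for (s in c(7, 8, 9)) {
    withr::with_seed(s, {
      x <- matrix(rnorm(6 * 10, mean = 0.6), 6)
    })
    res <- cluster_permutation_test(x, n_perm = 1024)
    expect_equal(res$method, "exhaustive")
    expect_equal(res$n_permutations, 64)
    oracle <- sort(enumerate_cluster_ps(x))
    expect_equal(sort(res$clusters$p), oracle, tolerance = 1e-12)
  }
})

test_that("permutation p-values respect sign-flip invariance and monotonicity", {
  withr::with_seed(11, {
    x <- matrix(rnorm(8 * 15, 0.5), 8)
  })
  res <- cluster_permutation_test(x, n_perm = 1024)
  res_flipped <- cluster_permutation_test(-x, n_perm = 1024)
  expect_equal(sort(res$clusters$p), sort(res_flipped$clusters$p))
  expect_equal(res$clusters$mass, -res_flipped$clusters$mass[
    order(match(res_flipped$clusters$start, res$clusters$start))])

  # adding a constant effect never increases the minimum cluster p
  withr::with_seed(12, {
    base <- matrix(rnorm(8 * 15), 8)
  })
  ps <- vapply(c(0, 0.5, 1, 2), function(eff) {
    r <- cluster_permutation_test(base + eff, n_perm = 1024)
    if (nrow(r$clusters)) min(r$clusters$p) else 1
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("2-D cluster test uses 4-connectivity and labels axes", {
  withr::with_seed(13, {
    arr <- array(rnorm(10 * 6 * 20), c(10, 6, 20))
    arr[, 2:4, 5:12] <- arr[, 2:4, 5:12] + 3
  })
  res <- cluster_permutation_test(arr, n_perm = 256, seed = 4,
                                  time = seq(0, 76, by = 4), freq = 5:10)
  top <- res$clusters[1, ]
  expect_lt(top$p, 0.05)
  expect_equal(top$freq_lo_hz, 6)
  expect_equal(top$freq_hi_hz, 8)
  expect_equal(top$start_ms, 16)
  expect_equal(top$end_ms, 44)

  # two diagonal-only blobs stay separate components under 4-connectivity
  m <- matrix(0L, 4, 4)
  m[1, 1] <- 1L
  m[2, 2] <- 1L
  lab <- wmreselect:::label_components_2d(as.integer(m), 4L, 4L)
  expect_equal(attr(lab, "n_labels"), 2)
})

test_that("paired cluster test equals the one-sample test on differences", {
  withr::with_seed(14, {
    a <- matrix(rnorm(10 * 25, 0.8), 10)
    b <- matrix(rnorm(10 * 25), 10)
  })
  pr <- paired_cluster_test(a, b, n_perm = 512, seed = 5)
  os <- cluster_permutation_test(a - b, n_perm = 512, seed = 5)
  expect_equal(pr$clusters, os$clusters)
  # a = b: no clusters
  same <- paired_cluster_test(a, a, n_perm = 64, seed = 6)
  expect_equal(nrow(same$clusters), 0)
  expect_error(paired_cluster_test(a, b[, 1:10]), "identical dimensions")
})

test_that("generalized ESD flags planted outliers and the canonical dataset", {
  # homogeneous scores: nothing flagged
  withr::with_seed(15, {
    clean <- rnorm(100)
    res_clean <- esd_reject(clean, max_outliers = 10)
    planted <- c(rnorm(99), 10)
    res_planted <- esd_reject(planted, max_outliers = 10)
  })
  expect_equal(res_clean$n_outliers, 0)
  expect_equal(res_planted$outliers, 100L)
  expect_equal(res_planted$n_outliers, 1L)

  # Rosner's canonical 54-point dataset: exactly 3 outliers, the largest values
  rosner <- c(-0.25, 0.68, 0.94, 1.15, 1.20, 1.26, 1.26, 1.34, 1.38, 1.43,
              1.49, 1.49, 1.55, 1.56, 1.58, 1.65, 1.69, 1.70, 1.76, 1.77,
              1.81, 1.91, 1.94, 1.96, 1.99, 2.06, 2.09, 2.10, 2.14, 2.15,
              2.23, 2.24, 2.26, 2.35, 2.37, 2.40, 2.47, 2.54, 2.62, 2.64,
              2.90, 2.92, 2.92, 2.93, 3.21, 3.26, 3.30, 3.59, 3.68, 4.30,
              4.64, 5.34, 5.42, 6.01)
  res <- esd_reject(rosner, max_outliers = 10)
  expect_equal(res$n_outliers, 3L)
  expect_equal(sort(rosner[res$outliers]), c(5.34, 5.42, 6.01))
  # first three studentized extremes match the published values
  expect_equal(res$steps$R[1:3], c(3.118, 2.942, 3.179), tolerance = 1e-3)

  expect_error(esd_reject(c(1, 2, NA)), "finite")
  expect_error(esd_reject(rnorm(20), max_outliers = 10), "half")
})
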