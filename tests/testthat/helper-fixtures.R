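# Shared small fixtures, built once per test run.

small_cfg <- function(n_participants = 2, n_trials = 48, seed = 11) {
  task_config(n_participants = n_participants,
              n_trials_per_participant = n_trials, seed = seed)
}

# brute-force orientation error: minimize |delta + 180 k| over integer k
bf_orientation_error <- function(a, b) {
  vapply(a - b, function(d) min(abs(d + 180 * (-6:6))), numeric(1))
}

# brute-force cross-correlation z[k] = sum_i x[i] y[i-k], full lag range
bf_xcorr <- function(x, y) {
  n <- length(x)
  vapply(-(n - 1):(n - 1), function(k) {
    s <- 0
    for (i in seq_len(n)) {
      j <- i - k
      if (j >= 1 && j <= n) s <- s + x[i] * y[j]
    }
    s
  }, numeric(1))
}

# independent exhaustive sign-flip oracle for the 1-D cluster test:
# every cluster p from full enumeration, using its own clustering code
enumerate_cluster_ps <- function(data, cluster_alpha = 0.05) {
  n <- nrow(data)
  thr <- qt(1 - cluster_alpha / 2, n - 1)
  tvec <- function(m) {
    apply(m, 2, function(col) mean(col) / (sd(col) / sqrt(length(col))))
  }
  masses <- function(tv) {
    out <- numeric(0)
    cur <- 0
    cur_sign <- 0
    for (v in c(tv, 0)) {
      s <- if (v > thr) 1 else if (v < -thr) -1 else 0
      if (s != cur_sign) {
        if (cur_sign != 0) out <- c(out, cur)
        cur <- 0
        cur_sign <- s
      }
      if (s != 0) cur <- cur + v
    }
    out
  }
  obs <- masses(tvec(data))
  null_max <- vapply(0:(2^n - 1), function(bits) {
    signs <- ifelse(bitwAnd(bits, 2^(0:(n - 1))) > 0, -1, 1)
    mm <- masses(tvec(signs * data))
    if (length(mm)) max(abs(mm)) else 0
  }, numeric(1))
  vapply(obs, function(m) mean(null_max >= abs(m)), numeric(1))
}
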