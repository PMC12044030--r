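test_that("blink interpolation restores ramps and respects boundaries", {
  t_ms <- seq(0, 400, by = 4)
  ramp <- seq(0, 1, length.out = length(t_ms))
  tr <- ramp
  tr[40:50] <- 99
  out <- interpolate_blinks(tr, t_ms,
                            data.frame(start_ms = t_ms[40], end_ms = t_ms[50]))
  expect_equal(out, ramp, tolerance = 1e-12)

  # no blinks: identity
  expect_identical(interpolate_blinks(ramp, t_ms,
                                      data.frame(start_ms = double(),
                                                 end_ms = double())),
                   ramp)

  # step around a blink: interpolated values equal the connecting chord
  step <- c(rep(0, 50), rep(1, 51))
  out2 <- interpolate_blinks(step, t_ms,
                             data.frame(start_ms = 180, end_ms = 220),
                             pad_ms = 0)
  bad <- t_ms >= 180 & t_ms <= 220
  good <- which(!bad)
  lo <- max(good[good < min(which(bad))])
  hi <- min(good[good > max(which(bad))])
  chord <- approx(t_ms[c(lo, hi)], step[c(lo, hi)], xout = t_ms[bad])$y
  expect_equal(out2[bad], chord)

  # blink at the boundary: nearest-value extension
  out3 <- interpolate_blinks(ramp, t_ms,
                             data.frame(start_ms = 0, end_ms = 40))
  expect_equal(out3[1], out3[which(t_ms > 140)[1] - 1], tolerance = 1e-12)
})

test_that("gaze preprocessing baselines, smooths, and rejects excursions", {
  cfg <- task_config(n_participants = 1, n_trials_per_participant = 12,
                     seed = 121)
  tab <- make_trial_table(cfg)
  gz <- sample_gaze(tab, cfg, towardness_amp = 0, noise_sd = 0.1,
                    raw_rate_hz = 500, seed = 8)
  prep <- preprocess_gaze(gz)
  expect_equal(prep$sampling_rate_hz, 250)
  expect_equal(diff(prep$times_ms)[1], 4)
  expect_true(min(prep$times_ms) >= -200 && max(prep$times_ms) <= 4200)
  # baselining: pre-cue mean is zero per trial
  base <- prep$samples |>
    dplyr::filter(time_ms <= 0) |>
    dplyr::group_by(trial) |>
    dplyr::summarise(m = mean(x))
  expect_true(all(abs(base$m) < 1e-10))

  # a 3-degree excursion removes the trial; retention matches construction
  gz2 <- gz
  tr1 <- gz2$samples$trial == gz2$samples$trial[1]
  gz2$samples$x_left[tr1] <- 3
  gz2$samples$x_right[tr1] <- 3
  prep2 <- preprocess_gaze(gz2)
  expect_equal(prep2$retention$n_kept, prep$retention$n_kept - 1)

  # constant trace at fixation: all-zero epochs after baselining
  flat <- gz
  for (cc in c("x_left", "x_right", "y_left", "y_right")) {
    flat$samples[[cc]] <- 0.5
  }
  prep3 <- preprocess_gaze(flat)
  expect_true(all(abs(prep3$samples$x) < 1e-12))
})

test_that("towardness is the half difference and is antisymmetric", {
  samples <- tidyr::expand_grid(participant = 1L, trial = 1:4,
                                time_ms = c(0, 4, 8))
  samples$x <- ifelse(samples$trial <= 2, 2, -2)
  table <- tibble::tibble(participant = 1L, trial = 1:4,
                          cued_side = c("right", "right", "left", "left"))
  tw <- towardness(samples, table)
  expect_true(all(tw$towardness == 2))

  flipped <- table
  flipped$cued_side <- c("left", "left", "right", "right")
  tw2 <- towardness(samples, flipped)
  expect_equal(tw$towardness, -tw2$towardness)

  # identical distributions in both conditions: zero towardness
  same <- samples
  same$x <- rep(c(1, -1), 6)
  expect_true(all(abs(towardness(same, table)$towardness) < 1e-12))
})

test_that("planted towardness amplitude is recovered from a synthetic cohort", {
  cfg <- task_config(n_participants = 20, n_trials_per_participant = 24,
                     seed = 131)
  tab <- make_trial_table(cfg)
  gz <- sample_gaze(tab, cfg, towardness_amp = 0.1, noise_sd = 0.15,
                    raw_rate_hz = 250, seed = 9)
  tw <- towardness(preprocess_gaze(gz), tab)
  grp <- tw |>
    dplyr::group_by(time_ms) |>
    dplyr::summarise(m = mean(towardness))
  peak <- max(grp$m[grp$time_ms > 200 & grp$time_ms < 600])
  expect_lt(abs(peak - 0.1), 0.05)

  # null generator: group towardness statistically indistinguishable from 0
  gz0 <- sample_gaze(tab, cfg, towardness_amp = 0, noise_sd = 0.15,
                     raw_rate_hz = 250, seed = 10)
  tw0 <- towardness(preprocess_gaze(gz0), tab)
  mat <- course_matrix(tw0)
  res <- cluster_permutation_test(mat, n_perm = 256, seed = 11,
                                  time = attr(mat, "axis"))
  expect_true(nrow(res$clusters) == 0 || min(res$clusters$p) > 0.05)
})
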