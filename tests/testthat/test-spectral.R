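make_epochs_from_fn <- function(fn, n_trials = 4,
                                channels = c("PO7", "PO8"),
                                fs = 250, window = c(-200, 4200)) {
  t_ms <- seq(window[1], window[2], by = 1000 / fs)
  arr <- array(0, c(n_trials, length(channels), length(t_ms)))
  for (tr in seq_len(n_trials)) {
    for (ch in seq_along(channels)) arr[tr, ch, ] <- fn(t_ms, tr, ch)
  }
  epoch_array(list(arr), list(seq_len(n_trials)), channels, t_ms, fs)
}

test_that("Morlet decomposition has a fixed-duration window and finds pure tones", {
  # 300-ms window: 3 cycles at 10 Hz, 6 at 20 Hz (cycles = f * 0.3)
  expect_equal(10 * 0.3, 3)
  expect_equal(20 * 0.3, 6)

  ep <- make_epochs_from_fn(function(t, tr, ch) sin(2 * pi * 10 * t / 1000))
  tfr <- morlet_tfr(ep, freqs = c(6, 8, 10, 12, 14))
  pw <- apply(tfr$power[[1]][1, 1, , tfr$valid], 1, mean)
  expect_equal(which.max(pw), 3)           # ridge at 10 Hz
  ridge <- tfr$power[[1]][1, 1, 3, tfr$valid]
  expect_lt(sd(ridge) / mean(ridge), 0.01) # flat in time away from edges

  # zero signal: zero power
  ep0 <- make_epochs_from_fn(function(t, tr, ch) 0 * t)
  tfr0 <- morlet_tfr(ep0, freqs = c(8, 10))
  expect_true(all(tfr0$power[[1]] < 1e-20))

  # frequencies above Nyquist are rejected
  expect_error(morlet_tfr(ep, freqs = c(10, 200)), "Nyquist")
})

test_that("total wavelet power of white noise scales linearly with variance", {
  withr::with_seed(141, {
    base <- array(rnorm(6 * 2 * 1101), c(6, 2, 1101))
  })
  t_ms <- seq(-200, 4200, by = 4)
  pw <- vapply(c(1, 2, 3), function(s) {
    ep <- epoch_array(list(s * base), list(1:6), c("PO7", "PO8"), t_ms, 250)
    tfr <- morlet_tfr(ep, freqs = seq(5, 30, by = 5))
    mean(tfr$power[[1]][, , , tfr$valid])
  }, numeric(1))
  # power ~ variance: doubling and tripling the amplitude scales total
  # wavelet power by 4 and 9, well within 5%
  expect_equal(pw[2] / pw[1], 4, tolerance = 0.05)
  expect_equal(pw[3] / pw[1], 9, tolerance = 0.05)
})

test_that("lateralization index matches arithmetic and closed-form recovery", {
  # constructed power: contra = 1, ipsi = 3 -> index -50
  cfg <- small_cfg(n_participants = 1, n_trials = 8, seed = 151)
  tab <- make_trial_table(cfg)
  amp <- function(t, tr, ch) {
    contra_right_ch <- 1  # PO7 (left hemisphere) is contra to right side
    side <- tab$cued_side[tr]
    contra <- (side == "right" && ch == 1) || (side == "left" && ch == 2)
    a <- if (contra) 1 else sqrt(3)
    a * sin(2 * pi * 10 * t / 1000 + tr)
  }
  ep <- make_epochs_from_fn(amp, n_trials = 8)
  tfr <- morlet_tfr(ep, freqs = 8:12)
  lat <- lateralization_index(tfr, tab[1:8, ], c("PO7", "PO8"), "item_side")
  bc <- band_course(lat, "alpha")
  expect_equal(mean(bc$index[bc$valid]), -50, tolerance = 1)
  expect_true(all(abs(lat$index) <= 100, na.rm = TRUE))

  # antisymmetry under swapping condition labels
  tab_sw <- tab
  tab_sw$cued_side <- ifelse(tab$cued_side == "left", "right", "left")
  lat_sw <- lateralization_index(tfr, tab_sw[1:8, ], c("PO7", "PO8"),
                                 "item_side")
  expect_equal(lat$index, -lat_sw$index, tolerance = 1e-10)

  # equal power in both conditions: index 0
  ep_eq <- make_epochs_from_fn(function(t, tr, ch)
    sin(2 * pi * 10 * t / 1000 + tr + ch), n_trials = 8)
  lat_eq <- lateralization_index(morlet_tfr(ep_eq, freqs = 8:12),
                                 tab[1:8, ], c("PO7", "PO8"), "item_side")
  # identical power in both conditions: index numerically zero (sub-0.1%)
  expect_lt(max(abs(lat_eq$index[, , lat_eq$valid]), na.rm = TRUE), 0.1)
})

test_that("generator attenuation yields the analytic lateralization value", {
  a <- 0.3
  r <- (1 - a)^2
  analytic <- -100 * (1 - r) / (1 + r)
  eff <- neural_effect("alpha", c("PO7", "PO8"), a,
                       windows = data.frame(start_ms = 1000, end_ms = 3000,
                                            profile = "sustained",
                                            lock = "cue"))
  cfg <- task_config(n_participants = 3, n_trials_per_participant = 24,
                     seed = 161)
  tab <- make_trial_table(cfg)
  ep <- sample_epochs(tab, cfg, list(eff), noise_sd = 0.02, seed = 12)
  lat <- lateralization_index(morlet_tfr(ep, freqs = 8:12, decim = 4),
                              tab, c("PO7", "PO8"), "item_side")
  bc <- band_course(lat, "alpha")
  mid <- dplyr::filter(bc, time_ms > 1400, time_ms < 2800)
  expect_equal(mean(mid$index), analytic, tolerance = 2)
  # null attenuation: index ~ 0 at all times
  ep0 <- sample_epochs(tab, cfg, list(), noise_sd = 1, seed = 13)
  lat0 <- lateralization_index(morlet_tfr(ep0, freqs = 8:12, decim = 4),
                               tab, c("PO7", "PO8"), "item_side")
  expect_lt(abs(mean(lat0$index, na.rm = TRUE)), 3)
})

test_that("band course averages the band and topography localizes the effect", {
  lat <- structure(
    list(index = array(rep(c(2, 4, 6), each = 1),
                       c(1, 3, 5)),
         freqs = c(8, 10, 12), times_ms = seq(0, 16, 4),
         valid = rep(TRUE, 5), pair = c("PO7", "PO8"),
         basis = "item_side", participants = 1L),
    class = "tfr_lateralization"
  )
  lat$index[1, , ] <- matrix(c(2, 4, 6), 3, 5)
  bc <- band_course(lat, c(8, 12))
  expect_true(all(bc$index == 4))
  bc1 <- band_course(lat, c(10, 10))
  expect_true(all(bc1$index == 4))
  expect_error(band_course(lat, c(50, 60)), "no TFR frequencies")

  # topography: effect planted at PO7/PO8 only shows there, flips with labels
  eff <- neural_effect("alpha", c("PO7", "PO8"), 0.4,
                       windows = data.frame(start_ms = 500, end_ms = 2000,
                                            profile = "sustained",
                                            lock = "cue"))
  cfg <- task_config(n_participants = 2, n_trials_per_participant = 16,
                     seed = 171)
  tab <- make_trial_table(cfg)
  ep <- sample_epochs(tab, cfg, list(eff),
                      channels = c("PO7", "PO8", "C3", "C4"),
                      noise_sd = 0.3, seed = 14)
  tfr <- morlet_tfr(ep, freqs = 8:12, decim = 4)
  topo <- topography_contrast(tfr, tab, "item_side", "alpha",
                              windows_ms = c(800, 1800)) |>
    dplyr::group_by(channel) |>
    dplyr::summarise(index = mean(index))
  po <- abs(topo$index[topo$channel %in% c("PO7", "PO8")])
  cc <- abs(topo$index[topo$channel %in% c("C3", "C4")])
  expect_gt(min(po), max(cc))
  # sign flips when condition labels are swapped
  tab_sw <- tab
  tab_sw$cued_side <- ifelse(tab$cued_side == "left", "right", "left")
  topo_sw <- topography_contrast(tfr, tab_sw, "item_side", "alpha",
                                 windows_ms = c(800, 1800)) |>
    dplyr::group_by(channel) |>
    dplyr::summarise(index = mean(index))
  expect_equal(topo$index, -topo_sw$index, tolerance = 1e-10)
})

test_that("event-locked re-epoching is sample-exact and drops edge trials", {
  cfg <- small_cfg(n_participants = 1, n_trials = 6, seed = 181)
  tab <- make_trial_table(cfg)
  ep <- make_epochs_from_fn(function(t, tr, ch) t + 10000 * tr, n_trials = 6)
  events <- tibble::tibble(participant = 1L, trial = 1:6,
                           event_ms = c(1000, 2000, 3000, 100, 4100, NA))
  out <- epoch_around_event(ep, events, window_ms = c(-400, 400))
  # event at 100 and 4100 run past an epoch edge; NA event dropped
  expect_equal(attr(out, "dropped")$n_dropped, 3)
  expect_equal(out$trials[[1]], 1:3)
  expect_equal(out$times_ms, seq(-400, 400, by = 4))
  # sample-exact alignment against direct indexing
  for (j in 1:3) {
    expect_equal(out$data[[1]][j, 1, ],
                 seq(events$event_ms[j] - 400, events$event_ms[j] + 400,
                     by = 4) + 10000 * j)
  }
  # event at 0 with a window inside the epoch: identity on that window
  ev0 <- tibble::tibble(participant = 1L, trial = 1L, event_ms = 0)
  out0 <- epoch_around_event(ep, ev0, window_ms = c(-200, 200))
  src_idx <- which(ep$times_ms >= -200 & ep$times_ms <= 200)
  expect_equal(out0$data[[1]][1, 1, ], ep$data[[1]][1, 1, src_idx])
})
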