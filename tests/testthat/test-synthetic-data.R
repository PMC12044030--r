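test_that("trial table reproduces the blocked design proportions", {
  cfg <- task_config(n_participants = 1, n_trials_per_participant = 648,
                     seed = 21)
  tab <- make_trial_table(cfg)
  expect_equal(nrow(tab), 648)
  expect_equal(dplyr::n_distinct(tab$block), 27)
  blocks <- dplyr::distinct(tab, block, block_type)
  expect_equal(sum(blocks$block_type == "no-interruption"), 9)
  expect_equal(sum(blocks$block_type == "interruption"), 18)
  # onset conditions receive equal interruption-trial counts
  counts <- dplyr::count(dplyr::filter(tab, block_type == "interruption"),
                         onset_condition)
  expect_true(all(counts$n == 144))
  # tilt sign <-> response hand mapping on every row
  expect_true(all(sign(tab$target_orientation) ==
                    ifelse(tab$response_hand == "left", 1, -1)))
})

test_that("smallest exactly balanced design has one trial per side-by-hand cell", {
  cfg <- task_config(n_participants = 1, n_trials_per_participant = 4,
                     seed = 3)
  tab <- make_trial_table(cfg, interruption_fraction = 0)
  cells <- dplyr::count(tab, cued_side, response_hand)
  expect_equal(nrow(cells), 4)
  expect_true(all(cells$n == 1))
})

test_that("cued side and response hand are counterbalanced", {
  cfg <- task_config(n_participants = 4, n_trials_per_participant = 144,
                     seed = 8)
  tab <- make_trial_table(cfg)
  r <- cor(tab$cued_side == "right", tab$response_hand == "right")
  expect_lt(abs(r), 0.06)
  per_cond <- tab |>
    dplyr::count(onset_condition, cued_side, response_hand) |>
    dplyr::group_by(onset_condition) |>
    dplyr::summarise(spread = max(n) - min(n))
  expect_true(all(per_cond$spread <= 2))
})

test_that("generators are seed-deterministic", {
  cfg <- small_cfg(seed = 77)
  t1 <- make_trial_table(cfg)
  t2 <- make_trial_table(cfg)
  expect_identical(t1, t2)
  expect_identical(sample_reports(t1, seed = 5), sample_reports(t2, seed = 5))
  g1 <- sample_gaze(t1[1:6, ], cfg, raw_rate_hz = 250, seed = 9)
  g2 <- sample_gaze(t1[1:6, ], cfg, raw_rate_hz = 250, seed = 9)
  expect_identical(g1$samples, g2$samples)
  e1 <- sample_epochs(t1[1:4, ], cfg, list(), seed = 13)
  e2 <- sample_epochs(t1[1:4, ], cfg, list(), seed = 13)
  expect_identical(e1$data, e2$data)
})

test_that("report mixture obeys its limiting cases", {
  cfg <- small_cfg(n_trials = 300, n_participants = 1, seed = 31)
  tab <- make_trial_table(cfg)
  # noiseless limit: reports equal targets
  noiseless <- sample_reports(tab, p_target = 1, p_nontarget = 0,
                              p_guess = 0, kappa = Inf, seed = 1)
  expect_equal(noiseless$reported_orientation,
               wrap_orientation(noiseless$target_orientation))
  # pure guessing: mean absolute error near the 45-degree chance level
  cfg2 <- task_config(n_participants = 1, n_trials_per_participant = 6000,
                      seed = 32)
  guess <- sample_reports(make_trial_table(cfg2), p_target = 0,
                          p_nontarget = 0, p_guess = 1, seed = 2)
  err <- orientation_error(guess$reported_orientation,
                           guess$target_orientation)
  expect_equal(mean(err), 45, tolerance = 0.04)
  expect_error(sample_reports(tab, 0.5, 0.1, 0.1), "sum to 1")
})

test_that("attractive bias shifts reports toward the interrupter", {
  cfg <- task_config(n_participants = 1, n_trials_per_participant = 2400,
                     seed = 41)
  tab <- sample_reports(make_trial_table(cfg), p_target = 1, p_nontarget = 0,
                        p_guess = 0, kappa = 30, bias_gain = 4, seed = 3)
  int <- dplyr::filter(tab, !is.na(interrupter_orientation))
  signed <- orientation_diff(int$reported_orientation, int$target_orientation)
  diff_ti <- orientation_diff(int$interrupter_orientation,
                              int$target_orientation)
  expect_gt(mean(signed[diff_ti > 10 & diff_ti < 50]), 0.5)
  expect_lt(mean(signed[diff_ti < -10 & diff_ti > -50]), -0.5)
})

test_that("gaze generator plants recoverable deflections and blinks", {
  cfg <- task_config(n_participants = 1, n_trials_per_participant = 40,
                     seed = 51)
  tab <- make_trial_table(cfg)
  gz <- sample_gaze(tab, cfg, towardness_amp = 0.5, blink_rate = 0.5,
                    noise_sd = 0.05, raw_rate_hz = 250, seed = 4)
  expect_gt(nrow(gz$blinks), 0)
  # saturated segments exist with configured duration
  sat <- gz$samples$x_left == 15
  expect_true(any(sat))
  # cue-locked deflection signed by cued side (excluding saturated samples)
  at_peak <- dplyr::filter(gz$samples, abs(time_ms - 400) < 20,
                           x_left != 15) |>
    dplyr::left_join(dplyr::select(tab, trial, cued_side), by = "trial")
  m <- tapply((at_peak$x_left + at_peak$x_right) / 2, at_peak$cued_side, mean)
  expect_gt(m[["right"]], 0.3)
  expect_lt(m[["left"]], -0.3)
})

test_that("epoch generator rejects unknown channels and honours null effects", {
  cfg <- small_cfg(n_participants = 1, n_trials = 8, seed = 61)
  tab <- make_trial_table(cfg)
  eff <- neural_effect("alpha", c("PO7", "PO8"), 0.3,
                       windows = data.frame(start_ms = 200, end_ms = 800,
                                            profile = "transient",
                                            lock = "cue"))
  expect_error(sample_epochs(tab, cfg, list(eff), channels = c("C3", "C4")),
               "pair not contained")
  ep <- sample_epochs(tab, cfg, list(), seed = 6)
  expect_s3_class(ep, "epoch_array")
  expect_equal(dim(ep$data[[1]])[1], 8)
})
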