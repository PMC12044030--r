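test_that("exclusion rules remove the right trials and flag the right datasets", {
  cfg <- small_cfg(n_participants = 2, n_trials = 60, seed = 71)
  tab <- sample_reports(make_trial_table(cfg), seed = 1)
  tab$interrupter_correct[tab$block_type == "interruption"] <- TRUE
  tab$interrupter_rt_ms[tab$block_type == "interruption"] <- 400
  tab$rt_probe_ms <- 700

  clean <- apply_exclusions(tab)
  expect_equal(nrow(clean$table), nrow(tab))
  expect_true(all(!clean$report$flag_rejection))
  expect_length(clean$flagged, 0)

  # a 6000 ms probe RT trial is removed by the absolute rule
  tab2 <- tab
  tab2$rt_probe_ms[5] <- 6000
  out2 <- apply_exclusions(tab2)
  expect_equal(nrow(out2$table), nrow(tab) - 1)
  expect_false(5 %in% out2$table$trial[out2$table$participant ==
                                         tab2$participant[5]])

  # participant 1 constructed with 20% bad interrupter trials gets flagged
  tab3 <- tab
  p1_int <- which(tab3$participant == 1 & tab3$block_type == "interruption")
  bad <- p1_int[seq_len(ceiling(0.20 * 60))]
  tab3$interrupter_correct[bad] <- FALSE
  out3 <- apply_exclusions(tab3)
  expect_true(1 %in% out3$flagged)
  expect_false(2 %in% out3$flagged)
  expect_equal(out3$report$n_removed[out3$report$participant == 1],
               length(bad))
})

test_that("mixture fit recovers limiting cases and generator parameters", {
  # reports identical to targets: p_target -> 1
  err0 <- rep(0, 200) + rnorm(200, 0, 1e-6)
  f0 <- fit_mixture(err0, runif(200, -90, 90))
  expect_gt(f0$p_target, 0.98)
  expect_lt(f0$p_guess, 0.02)

  # uniform reports: p_guess -> 1
  withr::with_seed(91, {
    fu <- fit_mixture(runif(400, -90, 90), runif(400, -90, 90))
  })
  expect_gt(fu$p_guess, 0.9)

  # parameter recovery at generator values (0.95, 0.02, 0.03), sd 10 deg
  withr::with_seed(92, {
    cfg <- task_config(n_participants = 1, n_trials_per_participant = 900,
                       seed = 92)
    tab <- sample_reports(make_trial_table(cfg), 0.95, 0.02, 0.03,
                          kappa = 8.2)
    int <- dplyr::filter(tab, !is.na(interrupter_orientation))
    f <- fit_mixture(
      orientation_diff(int$reported_orientation, int$target_orientation),
      orientation_diff(int$reported_orientation, int$interrupter_orientation)
    )
  })
  expect_equal(f$p_target, 0.95, tolerance = 0.04)
  expect_lt(abs(f$p_nontarget - 0.02), 0.03)
  expect_lt(abs(f$p_guess - 0.03), 0.03)
  expect_equal(f$kappa, 8.2, tolerance = 0.25)

  # proportions always sum to one
  expect_equal(f$p_target + f$p_nontarget + f$p_guess, 1, tolerance = 1e-6)
})

test_that("mixture log-likelihood dominates the nested target-only model", {
  withr::with_seed(93, {
    err_t <- wrap_orientation(c(rnorm(300, 0, 12), runif(60, -90, 90)))
    err_n <- runif(360, -90, 90)
    full <- fit_mixture(err_t, err_n)
    # target-only model at its own ML optimum (p fixed to 1)
    th <- 2 * err_t * pi / 180
    nll <- function(logk) {
      k <- exp(logk)
      -sum(k * (cos(th) - 1) -
             log(2 * pi * besselI(k, 0, expon.scaled = TRUE)))
    }
    opt <- optimize(nll, c(-5, 10))
  })
  expect_gte(full$log_likelihood, -opt$objective - 1e-6)
})

test_that("degenerate mixture input returns a boundary fit with a warning", {
  expect_warning(f <- fit_mixture(rep(0, 50), rep(10, 50)), "Degenerate")
  expect_true(f$boundary)
  expect_equal(f$p_target, 1)
})

test_that("response-bias curve recovers sign of attraction and odd symmetry", {
  cfg <- task_config(n_participants = 4, n_trials_per_participant = 300,
                     seed = 101)
  tab <- sample_reports(make_trial_table(cfg), p_target = 1, p_nontarget = 0,
                        p_guess = 0, kappa = 25, bias_gain = 4, seed = 5)
  curve <- response_bias_curve(tab)
  grp <- curve |>
    dplyr::filter(!is.na(bias)) |>
    dplyr::group_by(bin_center) |>
    dplyr::summarise(m = mean(bias))
  expect_gt(mean(grp$m[grp$bin_center > 10 & grp$bin_center < 60]), 0)
  expect_lt(mean(grp$m[grp$bin_center < -10 & grp$bin_center > -60]), 0)

  # mirror relabeling of the stimulus axis reflects the curve exactly
  mirrored <- tab
  mirrored$target_orientation <- wrap_orientation(-tab$target_orientation)
  mirrored$interrupter_orientation <-
    wrap_orientation(-tab$interrupter_orientation)
  mirrored$reported_orientation <- wrap_orientation(-tab$reported_orientation)
  curve_m <- response_bias_curve(mirrored)
  a <- dplyr::arrange(as.data.frame(curve), participant, bin_center)
  b <- dplyr::arrange(as.data.frame(curve_m), participant, -bin_center)
  expect_equal(a$bias, -b$bias, tolerance = 1e-10)

  # a zero-bias generator yields a flat group curve
  tab0 <- sample_reports(tab, p_target = 1, p_nontarget = 0, p_guess = 0,
                         kappa = 25, bias_gain = 0, seed = 6)
  grp0 <- response_bias_curve(tab0) |>
    dplyr::filter(!is.na(bias)) |>
    dplyr::group_by(bin_center) |>
    dplyr::summarise(m = mean(bias))
  expect_lt(max(abs(grp0$m)), 1.5)
})

test_that("empty bias-curve bins are reported as missing, never zero", {
  tab <- tibble::tibble(
    participant = 1, trial = 1:20,
    target_orientation = rep(10, 20),
    interrupter_orientation = rep(20, 20),  # all diffs at +10
    reported_orientation = rep(12, 20)
  )
  curve <- response_bias_curve(tab)
  far <- dplyr::filter(curve, abs(wrap_orientation(10 - bin_center)) > 22.5)
  expect_true(all(is.na(far$bias)))
  expect_true(all(far$n_trials == 0))
})

test_that("chance and condition tests match closed forms", {
  # constructed pairs: differences all +1 with known sd
  x <- c(10, 11, 12, 13)
  y <- x + 1
  res <- t_test_d(y, x)
  expect_equal(res$estimate, 1)
  expect_true(res$zero_variance)

  x2 <- c(10, 12, 14)
  y2 <- x2 + c(1, 2, 3)
  res2 <- t_test_d(y2, x2)
  d <- c(1, 2, 3)
  expect_equal(res2$t, mean(d) / (sd(d) / sqrt(3)))
  expect_equal(res2$cohens_d, mean(d) / sd(d))
  expect_equal(res2$p_value, t.test(d)$p.value)

  # identical condition means: t = 0, d = 0
  res3 <- t_test_d(c(1, 2, 3, 4), c(4, 3, 2, 1) + c(-3, -1, 1, 3))
  expect_equal(res3$t, 0)
  expect_equal(res3$cohens_d, 0)

  cfg <- small_cfg(n_participants = 3, n_trials = 48, seed = 111)
  tab <- sample_reports(make_trial_table(cfg), seed = 7)
  out <- chance_and_condition_tests(tab)
  expect_true(all(c("no-interruption vs chance", "interruption vs chance",
                    "interruption vs no-interruption") %in% out$test))
  expect_true(all(out$estimate[grepl("chance", out$test)] < 45))
})
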