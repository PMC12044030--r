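#' Trial-exclusion rules for continuous-report behavior
#'
#' Configuration of the a-priori preprocessing rules: probe responses
#' slower than an absolute ceiling (default 5000 ms) or more than
#' `rt_sd_mult` (default 2.5) standard deviations above the participant's
#' mean RT are removed, as are interruption trials on which the
#' interrupting task was answered wrongly, too late (after
#' `interrupter_deadline_ms`), or not at all. Participants lose their whole
#' dataset flag if more than `max_rejected_fraction` of trials are removed
#' or if their mean reproduction error reaches `max_condition_error_deg`
#' (the chance level) in any condition.
#'
#' @param rt_abs_max_ms Absolute probe-RT ceiling (ms).
#' @param rt_sd_mult RT rejection threshold in within-participant SDs.
#' @param interrupter_deadline_ms Response deadline of the interrupting task.
#' @param max_rejected_fraction Dataset-level rejection-fraction flag.
#' @param max_condition_error_deg Dataset-level mean-error flag (degrees).
#' @return An `exclusion_config` list.
#' @export
exclusion_config <- function(rt_abs_max_ms = 5000,
                             rt_sd_mult = 2.5,
                             interrupter_deadline_ms = 800,
                             max_rejected_fraction = 0.15,
                             max_condition_error_deg = 45) {
  vals <- c(rt_abs_max_ms, rt_sd_mult, interrupter_deadline_ms,
            max_rejected_fraction, max_condition_error_deg)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All exclusion thresholds must be positive and finite.")
  }
  structure(list(rt_abs_max_ms = rt_abs_max_ms,
                 rt_sd_mult = rt_sd_mult,
                 interrupter_deadline_ms = interrupter_deadline_ms,
                 max_rejected_fraction = max_rejected_fraction,
                 max_condition_error_deg = max_condition_error_deg),
            class = "exclusion_config")
}

#' Apply behavioral trial exclusions
#'
#' Removes trials violating the probe-RT and interrupter-response rules in
#' [exclusion_config()] and reports, per participant, how many trials each
#' rule removed, together with dataset-level flags (excess rejection
#' fraction; mean reproduction error at or above chance in any condition).
#'
#' @param table Trial table with `participant`, `rt_probe_ms`,
#'   `block_type`, `interrupter_correct`, `interrupter_rt_ms`; the
#'   condition-error flag additionally uses `reported_orientation`,
#'   `target_orientation`, and `onset_condition` when present.
#' @param cfg An [exclusion_config()].
#' @return List with `table` (the retained trials), `report`
#'   (per-participant tibble: totals, per-rule counts, rejected fraction,
#'   flags), and `flagged` (ids of participants whose dataset any flag
#'   rejects).
#' @examples
#' cfg <- task_config(n_participants = 2, n_trials_per_participant = 48)
#' tab <- sample_reports(make_trial_table(cfg), seed = 1)
#' apply_exclusions(tab)$report
#' @export
apply_exclusions <- function(table, cfg = exclusion_config()) {
  stopifnot(inherits(cfg, "exclusion_config"))
  check_columns(table, c("participant", "rt_probe_ms", "block_type",
                         "interrupter_correct", "interrupter_rt_ms"))
  tab <- table |>
    dplyr::group_by(.data$participant) |>
    dplyr::mutate(
      .rt_cut = mean(.data$rt_probe_ms, na.rm = TRUE) +
        cfg$rt_sd_mult * sd(.data$rt_probe_ms, na.rm = TRUE),
      .bad_rt = is.na(.data$rt_probe_ms) |
        .data$rt_probe_ms > cfg$rt_abs_max_ms |
        .data$rt_probe_ms > .data$.rt_cut,
      .bad_int = .data$block_type == "interruption" &
        (is.na(.data$interrupter_correct) | !.data$interrupter_correct |
           is.na(.data$interrupter_rt_ms) |
           .data$interrupter_rt_ms > cfg$interrupter_deadline_ms)
    ) |>
    dplyr::ungroup()

  report <- tab |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_bad_rt = sum(.data$.bad_rt),
      n_bad_interrupter = sum(.data$.bad_int & !.data$.bad_rt),
      n_removed = sum(.data$.bad_rt | .data$.bad_int),
      rejected_fraction = .data$n_removed / .data$n_trials,
      .groups = "drop"
    ) |>
    dplyr::mutate(flag_rejection =
                    .data$rejected_fraction > cfg$max_rejected_fraction)

  kept <- tab |>
    dplyr::filter(!.data$.bad_rt, !.data$.bad_int) |>
    dplyr::select(-".rt_cut", -".bad_rt", -".bad_int")

  if (all(c("reported_orientation", "target_orientation") %in% names(kept)) &&
      any(!is.na(kept$reported_orientation))) {
    cond_col <- if ("onset_condition" %in% names(kept)) "onset_condition"
                else "block_type"
    errs <- kept |>
      dplyr::filter(!is.na(.data$reported_orientation)) |>
      dplyr::group_by(.data$participant, .data[[cond_col]]) |>
      dplyr::summarise(mean_error = mean(orientation_error(
        .data$reported_orientation, .data$target_orientation)),
        .groups = "drop") |>
      dplyr::group_by(.data$participant) |>
      dplyr::summarise(max_condition_error = max(.data$mean_error),
                       .groups = "drop")
    report <- dplyr::left_join(report, errs, by = "participant") |>
      dplyr::mutate(flag_error = !is.na(.data$max_condition_error) &
                      .data$max_condition_error >= cfg$max_condition_error_deg)
  } else {
    report$max_condition_error <- NA_real_
    report$flag_error <- FALSE
  }
  flagged <- report$participant[report$flag_rejection | report$flag_error]
  list(table = kept, report = report, flagged = flagged)
}

#' Decompose report errors into target, swap, and guess components
#'
#' Maximum-likelihood fit of the three-component circular mixture that
#' underlies continuous-report errors: a von Mises component centred on the
#' target orientation, a von Mises ("swap") component centred on the
#' nontarget (interrupter) orientation, and a uniform guessing component.
#' The two von Mises components share one concentration `kappa`. Fitting is
#' expectation-maximization on doubled angles (orientations are 180-degree
#' periodic) with multiple random restarts; the best fit by log-likelihood
#' is returned.
#'
#' @param errors_to_target Signed report errors relative to the target
#'   (degrees, orientation space).
#' @param errors_to_nontarget Signed report errors relative to the
#'   nontarget, matched trial by trial, or `NULL` to fit a two-component
#'   (target + guess) model.
#' @param n_restarts Number of random EM restarts (an informed start from
#'   the data moments is always included).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @return A `mixture_fit` object: proportions `p_target`, `p_nontarget`,
#'   `p_guess`, shared concentration `kappa` (doubled-angle circle), the
#'   equivalent report `sd_deg` in orientation degrees, `log_likelihood`,
#'   `n`, and a `boundary` flag set when the fit ran into the degenerate
#'   kappa ceiling. Supports [tidy()] and [glance()].
#' @examples
#' err <- c(rnorm(200, 0, 8), runif(20, -90, 90))
#' fit_mixture(wrap_orientation(err))
#' @export
fit_mixture <- function(errors_to_target, errors_to_nontarget = NULL,
                        n_restarts = 10, tol = 1e-8, max_iter = 500) {
  th_t <- 2 * wrap_orientation(errors_to_target) * pi / 180
  n <- length(th_t)
  if (n < 2) abort("Need at least 2 trials to fit the mixture.")
  has_nt <- !is.null(errors_to_nontarget)
  if (has_nt && length(errors_to_nontarget) != n) {
    abort("`errors_to_target` and `errors_to_nontarget` must have equal length.")
  }
  th_n <- if (has_nt) 2 * wrap_orientation(errors_to_nontarget) * pi / 180
          else rep(0, n)

  kappa_cap <- 1e4
  degenerate <- sd(th_t) < 1e-10
  if (degenerate) {
    warn("Degenerate input (all errors identical): returning boundary fit.")
    ll <- n * log(dvonmises(0, kappa_cap))
    return(new_mixture_fit(1, 0, 0, kappa_cap, ll, n, boundary = TRUE))
  }

  starts <- c(
    list(list(p = c(0.8, if (has_nt) 0.1 else 0, NA), kappa = 5)),
    purrr::map(seq_len(n_restarts), function(i) {
      p_t <- runif(1, 0.3, 0.98)
      p_n <- if (has_nt) runif(1, 0, 1 - p_t) else 0
      list(p = c(p_t, p_n, NA), kappa = exp(runif(1, log(0.5), log(50))))
    })
  )
  best <- NULL
  for (st in starts) {
    p <- st$p
    p[3] <- 1 - p[1] - p[2]
    fit <- em_mixture(th_t, th_n, p, st$kappa, has_nt, tol, max_iter, kappa_cap)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  new_mixture_fit(best$p[1], best$p[2], best$p[3], best$kappa, best$ll, n,
                  boundary = best$kappa >= kappa_cap * 0.999)
}

em_mixture <- function(th_t, th_n, p, kappa, has_nt, tol, max_iter, kappa_cap) {
  n <- length(th_t)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    d_t <- p[1] * dvonmises(th_t, kappa)
    d_n <- if (has_nt) p[2] * dvonmises(th_n, kappa) else rep(0, n)
    d_g <- p[3] / (2 * pi)
    tot <- d_t + d_n + d_g
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
    ll_old <- ll
    g_t <- d_t / tot
    g_n <- d_n / tot
    p <- c(mean(g_t), mean(g_n), mean(1 - g_t - g_n))
    wsum <- sum(g_t) + sum(g_n)
    if (wsum > 1e-12) {
      rbar <- (sum(g_t * cos(th_t)) + sum(g_n * cos(th_n))) / wsum
      kappa <- a1inv(max(0, min(rbar, 1 - 1e-12)))
      kappa <- min(kappa, kappa_cap)
    }
  }
  list(p = p, kappa = kappa, ll = ll)
}

# von Mises density centred at 0, numerically stable for large kappa
dvonmises <- function(theta, kappa) {
  exp(kappa * (cos(theta) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

# Inverse of A1(kappa) = I1/I0: Best & Fisher approximation refined by
# uniroot on the exact Bessel ratio.
a1inv <- function(r) {
  if (r <= 0) return(0)
  if (r >= 1) return(Inf)
  # large-kappa asymptote A1(k) ~ 1 - 1/(2k); avoids Bessel underflow
  if (r > 0.999) return(1 / (2 * (1 - r)))
  k0 <- if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
        else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
        else 1 / (r^3 - 4 * r^2 + 3 * r)
  a1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE) - r
  lo <- max(k0 / 4, 1e-8); hi <- min(max(k0 * 4, 1), 1e6)
  if (a1(lo) > 0 || a1(hi) < 0) return(max(k0, 0))
  tryCatch(stats::uniroot(a1, c(lo, hi), tol = 1e-10)$root,
           error = function(e) max(k0, 0))
}

new_mixture_fit <- function(p_t, p_n, p_g, kappa, ll, n, boundary = FALSE) {
  structure(
    list(p_target = p_t, p_nontarget = p_n, p_guess = p_g,
         kappa = kappa,
         sd_deg = (1 / sqrt(max(kappa, 1e-12))) * 90 / pi,
         log_likelihood = ll, n = n, boundary = boundary),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit>  n =", x$n, if (x$boundary) " [boundary]" else "", "\n")
  cat(sprintf("  p_target = %.3f  p_nontarget = %.3f  p_guess = %.3f\n",
              x$p_target, x$p_nontarget, x$p_guess))
  cat(sprintf("  kappa = %.2f (report sd ~ %.1f deg)  logLik = %.2f\n",
              x$kappa, x$sd_deg, x$log_likelihood))
  invisible(x)
}

#' Per-participant mixture fits for a trial table
#'
#' Convenience wrapper fitting [fit_mixture()] to each participant's
#' interruption trials, using the signed errors of the report relative to
#' the target and to the interrupter orientation.
#'
#' @param table Trial table with filled `reported_orientation`.
#' @param ... Passed on to [fit_mixture()].
#' @return Tibble with one row per participant: the mixture proportions,
#'   `kappa`, `sd_deg`, `log_likelihood`, and `n`.
#' @export
fit_mixtures <- function(table, ...) {
  check_columns(table, c("participant", "reported_orientation",
                         "target_orientation", "interrupter_orientation"))
  table |>
    dplyr::filter(!is.na(.data$interrupter_orientation),
                  !is.na(.data$reported_orientation)) |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_mixture(
        orientation_diff(d$reported_orientation, d$target_orientation),
        orientation_diff(d$reported_orientation, d$interrupter_orientation),
        ...
      )
      tidy(fit)
    }) |>
    dplyr::ungroup()
}

#' Moving-window response-bias curve
#'
#' Quantifies whether reports are attracted toward (or repelled from) the
#' interrupter orientation. For each participant the signed report errors
#' (positive = anticlockwise) are demeaned across all interruption trials
#' (removing any constant response bias), then averaged in a moving window
#' (default step 5 degrees, width 45 degrees) over the signed
#' target-interrupter angular difference, which is positive when the
#' interrupter is tilted anticlockwise of the target. An attractive bias
#' shows as bias values whose sign matches the difference sign.
#'
#' @param table Trial table with filled reports; only rows with an
#'   interrupter orientation are used.
#' @param step Bin-centre spacing in degrees.
#' @param width Window width in degrees; the difference axis wraps with a
#'   180-degree period, so edge windows wrap around.
#' @return A `bias_curve` tibble: `participant`, `bin_center`, `bias`
#'   (mean demeaned signed error, degrees; `NA` for empty bins, never 0),
#'   and `n_trials`. Supports [autoplot()].
#' @examples
#' cfg <- task_config(n_participants = 3, n_trials_per_participant = 96)
#' tab <- sample_reports(make_trial_table(cfg), bias_gain = 3, seed = 2)
#' curve <- response_bias_curve(tab)
#' @export
response_bias_curve <- function(table, step = 5, width = 45) {
  check_columns(table, c("participant", "reported_orientation",
                         "target_orientation", "interrupter_orientation"))
  used <- table |>
    dplyr::filter(!is.na(.data$interrupter_orientation),
                  !is.na(.data$reported_orientation)) |>
    dplyr::mutate(
      signed_error = orientation_diff(.data$reported_orientation,
                                      .data$target_orientation),
      diff_ti = orientation_diff(.data$interrupter_orientation,
                                 .data$target_orientation)
    ) |>
    dplyr::group_by(.data$participant) |>
    dplyr::mutate(demeaned = .data$signed_error - mean(.data$signed_error)) |>
    dplyr::ungroup()
  if (!nrow(used)) abort("No trials with interrupter orientation present.")

  centers <- seq(-90, 90, by = step)
  out <- used |>
    dplyr::group_by(participant = .data$participant) |>
    dplyr::group_modify(function(d, key) {
      purrr::map_dfr(centers, function(bc) {
        sel <- abs(wrap_orientation(d$diff_ti - bc)) <= width / 2
        tibble::tibble(
          bin_center = bc,
          bias = if (any(sel)) mean(d$demeaned[sel]) else NA_real_,
          n_trials = sum(sel)
        )
      })
    }) |>
    dplyr::ungroup()
  structure(out, class = c("bias_curve", class(out)),
            step = step, width = width)
}

#' Chance-level and condition comparisons of reproduction errors
#'
#' Computes each participant's mean absolute reproduction error per block
#' type and runs the standard test battery: one-sample t tests of each
#' block type against the 45-degree chance level, and a paired t test of
#' no-interruption against interruption blocks. Cohen's d is the mean
#' divided by the standard deviation of the (difference) scores.
#'
#' @param table Trial table with filled reports.
#' @param chance_deg Chance level in degrees (45 for orientation space).
#' @return Tibble with one row per test: `test`, `estimate` (mean or mean
#'   difference, degrees), `t`, `df`, `p_value`, `cohens_d`, `n`.
#' @export
chance_and_condition_tests <- function(table, chance_deg = 45) {
  check_columns(table, c("participant", "block_type", "reported_orientation",
                         "target_orientation"))
  means <- table |>
    dplyr::filter(!is.na(.data$reported_orientation)) |>
    dplyr::group_by(.data$participant, .data$block_type) |>
    dplyr::summarise(mean_error = mean(orientation_error(
      .data$reported_orientation, .data$target_orientation)),
      .groups = "drop")
  if (dplyr::n_distinct(means$participant) < 2) {
    abort("Need at least 2 participants.")
  }
  wide <- tidyr::pivot_wider(means, names_from = "block_type",
                             values_from = "mean_error")
  out <- purrr::map_dfr(setdiff(names(wide), "participant"), function(bt) {
    res <- t_test_d(wide[[bt]] - chance_deg)
    dplyr::mutate(res, test = paste0(bt, " vs chance"),
                  estimate = .data$estimate + chance_deg)
  })
  if (all(c("no-interruption", "interruption") %in% names(wide))) {
    both <- wide[complete.cases(wide[c("no-interruption", "interruption")]), ]
    res <- t_test_d(both[["interruption"]] - both[["no-interruption"]])
    out <- dplyr::bind_rows(
      out, dplyr::mutate(res, test = "interruption vs no-interruption")
    )
  }
  dplyr::relocate(out, "test")
}
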