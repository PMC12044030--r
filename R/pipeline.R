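#' Configure a full simulation-and-analysis run
#'
#' Collects every knob of the end-to-end pipeline — cohort size, generator
#' effect sizes, statistical parameters, stage toggles, and the seed — into
#' a serializable list. `read_run_config()` / `write_run_config()` move the
#' same structure to and from YAML, so a run is fully reproducible from its
#' config file plus seed.
#'
#' @param n_participants,n_trials_per_participant Cohort dimensions.
#' @param alpha_attenuation,beta_attenuation Contralateral amplitude
#'   attenuation of the planted visual (alpha) and motor (beta) effects.
#' @param motor_delay_ms Planted latency of response-locked motor windows
#'   relative to visual ones.
#' @param noise_sd EEG background-noise standard deviation.
#' @param towardness_amp Gaze-bias amplitude (degrees); `NA` skips gaze.
#' @param p_target,p_nontarget,p_guess,kappa,bias_gain Report-mixture
#'   generator parameters (see [sample_reports()]).
#' @param n_perm,cluster_alpha Cluster-permutation parameters.
#' @param decim TFR time decimation for cluster statistics.
#' @param do_behavior,do_gaze,do_spectral,do_crosscorr Stage toggles.
#' @param seed Integer seed controlling the entire run.
#' @param out_dir Output directory, or `NULL` to keep results in memory.
#' @return A `run_config` list.
#' @export
run_config <- function(n_participants = 20,
                       n_trials_per_participant = 96,
                       alpha_attenuation = 0.35,
                       beta_attenuation = 0.3,
                       motor_delay_ms = 0,
                       noise_sd = 1,
                       towardness_amp = 0.1,
                       p_target = 0.95, p_nontarget = 0.02, p_guess = 0.03,
                       kappa = 8.2, bias_gain = 2,
                       n_perm = 1024, cluster_alpha = 0.05,
                       decim = 4,
                       do_behavior = TRUE, do_gaze = TRUE,
                       do_spectral = TRUE, do_crosscorr = TRUE,
                       seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(n_participants >= 2, n_trials_per_participant >= 12,
            n_perm >= 10, cluster_alpha > 0, cluster_alpha < 1)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# The generator effects implementing the study's expected pattern: a
# transient contralateral alpha attenuation after the cue and again after
# the interrupter response, and a beta attenuation that is transient after
# the cue but sustained after the response.
default_effects <- function(config) {
  list(
    neural_effect(
      "alpha", c("PO7", "PO8"), config$alpha_attenuation,
      windows = tibble::tibble(
        start_ms = c(200, 0), end_ms = c(800, 400),
        profile = c("transient", "transient"),
        lock = c("cue", "response")
      )
    ),
    neural_effect(
      "beta", c("C3", "C4"), config$beta_attenuation,
      windows = tibble::tibble(
        start_ms = c(200, 0), end_ms = c(1000, 2400),
        profile = c("transient", "sustained"),
        lock = c("cue", "response")
      ),
      motor_delay_ms = config$motor_delay_ms
    )
  )
}

#' Run the full simulation and analysis pipeline
#'
#' Executes the three analysis arcs end to end on a synthetic cohort:
#' (1) behavior — exclusions, chance-level and condition tests, mixture
#' decomposition, response-bias curve with a cluster test over bins;
#' (2) gaze — preprocessing and towardness per interrupter onset with
#' cluster tests; (3) EEG — cue-locked alpha/beta lateralization courses
#' per onset condition with cluster tests and the onset-ordering summary,
#' the response-locked analysis (re-epoched -400..400 ms around the
#' interrupter response), and the per-participant visual-motor
#' cross-correlation with the group zero-lag test. All randomness derives
#' from `config$seed`; rerunning a config reproduces every table.
#'
#' @param config A [run_config()].
#' @return A `wm_pipeline` list of stage results (`trials`, `behavior`,
#'   `gaze`, `spectral`, `crosscorr`, `provenance`). When
#'   `config$out_dir` is set, result tables (CSV), cluster reports (JSON),
#'   and the provenance log are also written there.
#' @export
run_reselection_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  t0 <- Sys.time()

  cfg <- task_config(
    n_participants = config$n_participants,
    n_trials_per_participant = config$n_trials_per_participant,
    seed = config$seed
  )
  table <- make_trial_table(cfg)
  table <- sample_reports(table, config$p_target, config$p_nontarget,
                          config$p_guess, config$kappa, config$bias_gain)
  results <- list(trials = table)

  if (config$do_behavior) {
    excl <- apply_exclusions(table)
    bias <- response_bias_curve(excl$table)
    bias_mat <- course_matrix(bias, axis = "bin_center", value = "bias")
    bias_test <- cluster_permutation_test(
      bias_mat[, colSums(is.na(bias_mat)) == 0, drop = FALSE],
      n_perm = config$n_perm, cluster_alpha = config$cluster_alpha,
      time = attr(bias_mat, "axis")[colSums(is.na(bias_mat)) == 0],
      seed = config$seed
    )
    results$behavior <- list(
      exclusions = excl$report,
      tests = chance_and_condition_tests(excl$table),
      mixture = fit_mixtures(excl$table),
      bias_curve = bias,
      bias_cluster_test = bias_test
    )
    table_kept <- excl$table
  } else {
    table_kept <- table
  }

  if (config$do_gaze && is.finite(config$towardness_amp)) {
    gz <- sample_gaze(table, cfg, towardness_amp = config$towardness_amp,
                      blink_rate = 0.2, raw_rate_hz = 250)
    prep <- preprocess_gaze(gz)
    tw_by_onset <- purrr::map(
      set_names_by(onset_condition_labels(length(cfg$interrupter_onsets_ms))),
      function(oc) {
        tw <- towardness(prep,
                         dplyr::filter(table, .data$onset_condition == oc))
        mat <- course_matrix(tw)
        test <- cluster_permutation_test(
          mat, n_perm = config$n_perm, cluster_alpha = config$cluster_alpha,
          time = attr(mat, "axis"), seed = config$seed
        )
        list(towardness = tw, cluster_test = test)
      }
    )
    results$gaze <- list(retention = prep$retention, by_onset = tw_by_onset)
  }

  if (config$do_spectral) {
    epochs <- sample_epochs(table, cfg, default_effects(config),
                            noise_sd = config$noise_sd)
    results$spectral <- spectral_arc(epochs, table_kept, cfg, config)
    if (config$do_crosscorr) {
      results$crosscorr <- crosscorr_arc(results$spectral$response_locked,
                                         config)
    }
  }

  results$provenance <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("wmreselect")),
    r_version = R.version.string,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  out <- structure(results, class = "wm_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  out
}

set_names_by <- function(x) stats::setNames(x, x)

# Cue-locked per-onset and response-locked lateralization analyses.
spectral_arc <- function(epochs, table, cfg, config) {
  onset_labels <- onset_condition_labels(length(cfg$interrupter_onsets_ms))

  analyse <- function(ep, tab) {
    tfr_a <- morlet_tfr(ep, freqs = 8:12, channels = c("PO7", "PO8"),
                        decim = config$decim)
    tfr_b <- morlet_tfr(ep, freqs = 13:30, channels = c("C3", "C4"),
                        decim = config$decim)
    alpha <- band_course(lateralization_index(tfr_a, tab,
                                              c("PO7", "PO8"), "item_side"),
                         "alpha")
    beta <- band_course(lateralization_index(tfr_b, tab,
                                             c("C3", "C4"), "response_hand"),
                        "beta")
    list(alpha = alpha, beta = beta,
         alpha_test = band_cluster_test(alpha, config),
         beta_test = band_cluster_test(beta, config))
  }

  by_onset <- purrr::map(set_names_by(onset_labels), function(oc) {
    keep <- dplyr::filter(table, .data$onset_condition == oc)
    analyse(filter_epochs(epochs, keep), keep)
  })

  int_tab <- dplyr::filter(table, !is.na(.data$onset_ms),
                           !is.na(.data$interrupter_rt_ms))
  resp_epochs <- epoch_around_event(
    filter_epochs(epochs, int_tab),
    dplyr::transmute(int_tab, .data$participant, .data$trial,
                     event_ms = .data$onset_ms + .data$interrupter_rt_ms)
  )
  response_locked <- analyse(resp_epochs, int_tab)

  onset_summary <- compare_onset_conditions(
    purrr::map(by_onset, "alpha_test"),
    stats::setNames(cfg$interrupter_onsets_ms, onset_labels)
  )
  list(by_onset = by_onset, response_locked = response_locked,
       onset_summary = onset_summary)
}

band_cluster_test <- function(course, config) {
  mat <- course_matrix(dplyr::filter(course, .data$valid), value = "index")
  cluster_permutation_test(
    mat, n_perm = config$n_perm, cluster_alpha = config$cluster_alpha,
    time = attr(mat, "axis"), seed = config$seed
  )
}

# Per-participant cross-correlation between the response-locked visual and
# motor courses, plus the group zero-lag test.
crosscorr_arc <- function(response_locked, config) {
  wide <- dplyr::inner_join(
    dplyr::rename(dplyr::filter(response_locked$alpha, .data$valid),
                  visual = "index"),
    dplyr::select(dplyr::filter(response_locked$beta, .data$valid),
                  "participant", "time_ms", motor = "index"),
    by = c("participant", "time_ms")
  )
  fs <- 1000 / diff(sort(unique(wide$time_ms))[1:2])
  per_part <- wide |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(d, key) {
      xc <- normalized_xcorr(d$visual, d$motor, sampling_rate_hz = fs)
      tibble::tibble(peak_lag_ms = peak_lag(xc), xcorr = list(xc))
    }) |>
    dplyr::ungroup()
  list(peak_lags = dplyr::select(per_part, "participant", "peak_lag_ms"),
       xcorrs = per_part$xcorr,
       zero_lag_test = zero_lag_test(per_part$peak_lag_ms))
}

# Restrict an epoch_array to the (participant, trial) rows of a table.
filter_epochs <- function(epochs, keep) {
  stopifnot(inherits(epochs, "epoch_array"))
  check_columns(keep, c("participant", "trial"))
  sel_p <- which(epochs$participants %in% unique(keep$participant))
  data <- vector("list", length(sel_p))
  trials <- vector("list", length(sel_p))
  for (j in seq_along(sel_p)) {
    i <- sel_p[j]
    ids <- epochs$trials[[i]]
    keep_ids <- keep$trial[keep$participant == epochs$participants[i]]
    sel <- ids %in% keep_ids
    data[[j]] <- epochs$data[[i]][sel, , , drop = FALSE]
    trials[[j]] <- ids[sel]
  }
  epoch_array(data, trials, epochs$channels, epochs$times_ms,
              epochs$sampling_rate_hz, epochs$participants[sel_p])
}

#' Order reselection-cluster onsets across interrupter-onset conditions
#'
#' Extracts, for each onset condition, the start time of the post-
#' interrupter ("reselection") cluster — the first significant cluster
#' beginning after that condition's interrupter onset — and reports
#' whether the starts are strictly ordered across conditions. Conditions
#' without such a cluster are reported as missing, and no ordering is
#' claimed when any is missing or when starts tie.
#'
#' @param cluster_results Named list of `cluster_result` objects (one per
#'   onset condition, with time-labelled clusters).
#' @param onsets_ms Named numeric vector of interrupter onsets (ms), names
#'   matching `cluster_results`.
#' @param alpha Significance level for counting a cluster.
#' @return Tibble: `onset_condition`, `onset_ms`, `reselection_start_ms`,
#'   `p`; attribute `"ordered"` is `TRUE`, `FALSE`, or `NA` (not claimed).
#' @export
compare_onset_conditions <- function(cluster_results, onsets_ms,
                                     alpha = 0.05) {
  stopifnot(length(cluster_results) == length(onsets_ms),
            all(names(cluster_results) %in% names(onsets_ms)))
  out <- purrr::map_dfr(names(cluster_results), function(oc) {
    cl <- tidy(cluster_results[[oc]])
    if (!"start_ms" %in% names(cl)) cl$start_ms <- NA_real_
    sel <- cl[cl$p < alpha & !is.na(cl$start_ms) &
                cl$start_ms > onsets_ms[[oc]], , drop = FALSE]
    if (nrow(sel)) {
      first <- sel[which.min(sel$start_ms), ]
      tibble::tibble(onset_condition = oc, onset_ms = onsets_ms[[oc]],
                     reselection_start_ms = first$start_ms, p = first$p)
    } else {
      tibble::tibble(onset_condition = oc, onset_ms = onsets_ms[[oc]],
                     reselection_start_ms = NA_real_, p = NA_real_)
    }
  })
  out <- out[order(out$onset_ms), ]
  ordered <- if (anyNA(out$reselection_start_ms)) NA else
    !is.unsorted(out$reselection_start_ms, strictly = TRUE)
  attr(out, "ordered") <- ordered
  out
}

#' @export
print.wm_pipeline <- function(x, ...) {
  cat("<wm_pipeline> stages:",
      paste(setdiff(names(x), c("trials", "provenance")), collapse = ", "),
      "\n")
  cat("  trials:", nrow(x$trials), " config hash:",
      x$provenance$config_hash, "\n")
  cat("  elapsed:", round(x$provenance$elapsed_s, 1), "s\n")
  invisible(x)
}

write_pipeline_outputs <- function(results, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
  }
  wr(results$trials, "trial_table.csv")
  if (!is.null(results$behavior)) {
    wr(results$behavior$tests, "behavior_tests.csv")
    wr(results$behavior$mixture, "mixture_fits.csv")
    wr(results$behavior$bias_curve, "bias_curve.csv")
    jsonlite::write_json(tidy(results$behavior$bias_cluster_test),
                         file.path(config$out_dir, "bias_clusters.json"))
  }
  if (!is.null(results$gaze)) {
    purrr::iwalk(results$gaze$by_onset, function(res, oc) {
      wr(res$towardness, paste0("towardness_", oc, ".csv"))
      jsonlite::write_json(tidy(res$cluster_test),
                           file.path(config$out_dir,
                                     paste0("towardness_clusters_", oc,
                                            ".json")))
    })
  }
  if (!is.null(results$spectral)) {
    purrr::iwalk(results$spectral$by_onset, function(res, oc) {
      wr(res$alpha, paste0("alpha_course_", oc, ".csv"))
      wr(res$beta, paste0("beta_course_", oc, ".csv"))
      jsonlite::write_json(
        list(alpha = tidy(res$alpha_test), beta = tidy(res$beta_test)),
        file.path(config$out_dir, paste0("clusters_", oc, ".json"))
      )
    })
    wr(results$spectral$onset_summary, "onset_summary.csv")
  }
  if (!is.null(results$crosscorr)) {
    wr(results$crosscorr$peak_lags, "peak_lags.csv")
    wr(results$crosscorr$zero_lag_test, "zero_lag_test.csv")
  }
  jsonlite::write_json(results$provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(config$out_dir)
}
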