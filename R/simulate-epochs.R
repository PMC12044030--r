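#' Specify a lateralized oscillatory effect for the epoch generator
#'
#' Describes one band-limited effect that [sample_epochs()] plants in the
#' simulated EEG: an oscillation present at both channels of a left/right
#' pair whose amplitude at the channel *contralateral* to the relevant
#' trial feature (cued item side for the visual/alpha effect, required
#' response hand for the motor/beta effect) is attenuated inside specified
#' time windows. Attenuated contralateral power is what the downstream
#' lateralization index picks up as a negative deflection.
#'
#' @param band Frequency band, `c(low, high)` in Hz, or `"alpha"` (8-12) /
#'   `"beta"` (13-30).
#' @param channel_pair Left/right channel pair, e.g. `c("PO7", "PO8")` or
#'   `c("C3", "C4")`.
#' @param contra_attenuation Fractional amplitude attenuation in [0, 1) of
#'   the contralateral channel inside the effect windows.
#' @param windows Tibble (or data frame) with columns `start_ms`, `end_ms`,
#'   `profile` (`"transient"` = Hann bump, `"sustained"` = 100-ms ramp then
#'   hold), and `lock` (`"cue"` = absolute epoch time, `"response"` =
#'   relative to the interrupter response).
#' @param basis Trial feature that defines contra/ipsi: `"item_side"`
#'   (cued_side) or `"response_hand"`. Default: alpha-range bands use
#'   `"item_side"`, higher bands `"response_hand"`.
#' @param motor_delay_ms Extra latency added to response-locked windows
#'   (models a motor-signal lag).
#' @param amplitude Oscillation amplitude in the units of the noise.
#' @return A `neural_effect` list used by [sample_epochs()].
#' @examples
#' neural_effect("alpha", c("PO7", "PO8"), 0.3,
#'               windows = data.frame(start_ms = 200, end_ms = 800,
#'                                    profile = "transient", lock = "cue"))
#' @export
neural_effect <- function(band, channel_pair, contra_attenuation,
                          windows, basis = NULL, motor_delay_ms = 0,
                          amplitude = 1) {
  if (is.character(band)) {
    band <- switch(band, alpha = c(8, 12), beta = c(13, 30),
                   abort("Unknown band name; use 'alpha', 'beta' or c(lo, hi)."))
  }
  stopifnot(length(band) == 2, band[1] < band[2], length(channel_pair) == 2)
  if (contra_attenuation < 0 || contra_attenuation >= 1) {
    abort("`contra_attenuation` must be in [0, 1).")
  }
  windows <- tibble::as_tibble(windows)
  check_columns(windows, c("start_ms", "end_ms", "profile", "lock"))
  if (!all(windows$profile %in% c("transient", "sustained"))) {
    abort("Window profiles must be 'transient' or 'sustained'.")
  }
  if (!all(windows$lock %in% c("cue", "response"))) {
    abort("Window locks must be 'cue' or 'response'.")
  }
  hemi <- channel_hemisphere(channel_pair)
  if (!setequal(hemi, c("left", "right"))) {
    abort("`channel_pair` must contain one left- and one right-hemisphere channel.")
  }
  if (is.null(basis)) {
    basis <- if (mean(band) <= 12.5) "item_side" else "response_hand"
  }
  basis <- match.arg(basis, c("item_side", "response_hand"))
  structure(
    list(band = as.numeric(band), channel_pair = as.character(channel_pair),
         contra_attenuation = contra_attenuation, windows = windows,
         basis = basis, motor_delay_ms = motor_delay_ms,
         amplitude = amplitude),
    class = "neural_effect"
  )
}

#' Simulate epoched multichannel oscillatory EEG data
#'
#' Generates an [epoch_array()] for every trial of a trial table: each
#' channel carries 1/f-like background noise plus, for every
#' [neural_effect()], a band-limited oscillation (random frequency within
#' the band and random phase per trial and channel) whose amplitude at the
#' channel contralateral to the relevant trial feature is reduced by
#' `contra_attenuation` inside the effect windows. Response-locked windows
#' are placed at interrupter onset + that trial's simulated reaction time
#' (+ `motor_delay_ms`); trials without an interrupter response carry no
#' response-locked modulation.
#'
#' @param table Trial table from [make_trial_table()].
#' @param cfg A [task_config()].
#' @param effects List of [neural_effect()] specifications.
#' @param noise_sd Standard deviation of the 1/f background noise.
#' @param channels Channel labels to simulate; defaults to the union of all
#'   effect pairs (and `PO7/PO8/C3/C4` when `effects` is empty).
#' @param seed Optional integer seed for this step alone.
#' @return An [epoch_array()].
#' @examples
#' cfg <- task_config(n_participants = 2, n_trials_per_participant = 12)
#' tab <- make_trial_table(cfg)
#' eff <- neural_effect("alpha", c("PO7", "PO8"), 0.3,
#'                      windows = data.frame(start_ms = 200, end_ms = 800,
#'                                           profile = "transient",
#'                                           lock = "cue"))
#' ep <- sample_epochs(tab, cfg, list(eff), seed = 1)
#' @export
sample_epochs <- function(table, cfg, effects, noise_sd = 1,
                          channels = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "task_config"))
  check_columns(table, c("participant", "trial", "cued_side", "response_hand",
                         "onset_ms", "interrupter_rt_ms"))
  effects <- purrr::map(effects, function(e) {
    if (!inherits(e, "neural_effect")) abort("`effects` must be neural_effect objects.")
    e
  })
  if (is.null(channels)) {
    channels <- unique(c(unlist(purrr::map(effects, "channel_pair")),
                         if (!length(effects)) c("PO7", "PO8", "C3", "C4")))
  }
  for (e in effects) {
    if (!all(e$channel_pair %in% channels)) {
      abort("Effect channel pair not contained in the simulated channel set.")
    }
    cue_w <- e$windows[e$windows$lock == "cue", ]
    if (nrow(cue_w) && (any(cue_w$start_ms < cfg$epoch_window_ms[1]) ||
                        any(cue_w$end_ms > cfg$epoch_window_ms[2]))) {
      abort("Cue-locked effect windows must lie inside the epoch window.")
    }
  }
  t_ms <- seq(cfg$epoch_window_ms[1], cfg$epoch_window_ms[2],
              by = 1000 / cfg$sampling_rate_hz)
  ns <- length(t_ms)
  parts <- sort(unique(table$participant))

  with_seed_if(seed, {
    data <- vector("list", length(parts))
    trials <- vector("list", length(parts))
    for (i in seq_along(parts)) {
      rows <- which(table$participant == parts[i])
      arr <- array(0, c(length(rows), length(channels), ns))
      for (j in seq_along(rows)) {
        tr <- table[rows[j], ]
        for (ci in seq_along(channels)) {
          sig <- pink_noise(ns, noise_sd)
          for (e in effects) {
            ch_pos <- match(channels[ci], e$channel_pair)
            if (is.na(ch_pos)) next
            f <- runif(1, e$band[1], e$band[2])
            osc <- e$amplitude *
              sin(2 * pi * f * t_ms / 1000 + runif(1, 0, 2 * pi))
            env <- effect_envelope(e, tr, t_ms, channels[ci])
            sig <- sig + osc * env
          }
          arr[j, ci, ] <- sig
        }
      }
      data[[i]] <- arr
      trials[[i]] <- table$trial[rows]
    }
    epoch_array(data, trials, channels, t_ms, cfg$sampling_rate_hz, parts)
  })
}

# Amplitude envelope of an effect at one channel for one trial: 1 on the
# ipsilateral channel, 1 - a * w(t) on the contralateral one.
effect_envelope <- function(effect, trial_row, t_ms, channel) {
  label <- if (effect$basis == "item_side") trial_row$cued_side else
    trial_row$response_hand
  contra_hemi <- if (label == "right") "left" else "right"
  if (channel_hemisphere(channel) != contra_hemi) {
    return(rep(1, length(t_ms)))
  }
  w <- rep(0, length(t_ms))
  for (k in seq_len(nrow(effect$windows))) {
    win <- effect$windows[k, ]
    if (win$lock == "response") {
      if (is.na(trial_row$onset_ms) || is.na(trial_row$interrupter_rt_ms)) next
      shift <- trial_row$onset_ms + trial_row$interrupter_rt_ms +
        effect$motor_delay_ms
      lo <- win$start_ms + shift
      hi <- win$end_ms + shift
    } else {
      lo <- win$start_ms
      hi <- win$end_ms
    }
    w <- pmax(w, window_profile(t_ms, lo, hi, win$profile))
  }
  1 - effect$contra_attenuation * w
}

window_profile <- function(t_ms, lo, hi, profile) {
  out <- rep(0, length(t_ms))
  sel <- t_ms >= lo & t_ms <= hi
  if (!any(sel)) return(out)
  if (profile == "transient") {
    out[sel] <- 0.5 - 0.5 * cos(2 * pi * (t_ms[sel] - lo) / (hi - lo))
  } else {
    out[sel] <- pmin(1, (t_ms[sel] - lo) / 100)
  }
  out
}

# 1/f-amplitude (power ~ 1/f) Gaussian background noise via spectral shaping.
pink_noise <- function(n, sd) {
  if (sd <= 0) return(numeric(n))
  nfft <- n
  white <- rnorm(nfft)
  spec <- fft(white)
  f <- c(1, seq_len(nfft - 1))
  f <- pmin(f, nfft - f + 1)          # mirror for negative frequencies
  spec <- spec / sqrt(f)
  out <- Re(fft(spec, inverse = TRUE)) / nfft
  sd * (out - mean(out)) / stats::sd(out)
}
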