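#' Epoched multichannel time-series container
#'
#' `epoch_array()` stores cleaned, epoched multichannel data for a cohort:
#' one `trials x channels x samples` numeric array per participant, a
#' shared channel set and time axis, and the per-participant trial ids that
#' link each array row to a trial table. Participants may contribute
#' different numbers of trials.
#'
#' @param data List (one element per participant) of 3-D arrays with
#'   dimensions trials x channels x samples.
#' @param trials List of integer vectors: the trial-table `trial` ids
#'   matching the first dimension of each array.
#' @param channels Character vector of channel labels (e.g. `"PO7"`).
#' @param times_ms Numeric time axis (ms), shared by all participants.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param participants Participant ids (defaults to `seq_along(data)`).
#' @return An object of class `epoch_array`.
#' @seealso [sample_epochs()], [epoch_around_event()], [morlet_tfr()]
#' @export
epoch_array <- function(data, trials, channels, times_ms, sampling_rate_hz,
                        participants = seq_along(data)) {
  stopifnot(is.list(data), is.list(trials),
            length(data) == length(trials),
            length(data) == length(participants))
  for (i in seq_along(data)) {
    d <- dim(data[[i]])
    if (length(d) != 3 || d[2] != length(channels) || d[3] != length(times_ms)) {
      abort("Each participant array must be trials x channels x samples.")
    }
    if (d[1] != length(trials[[i]])) {
      abort("Trial ids must match the first array dimension.")
    }
  }
  structure(
    list(data = data, trials = trials, channels = as.character(channels),
         times_ms = as.numeric(times_ms),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         participants = participants),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  nt <- vapply(x$data, function(a) dim(a)[1], integer(1))
  cat("<epoch_array> ", length(x$data), " participants, ",
      min(nt), "-", max(nt), " trials, ",
      length(x$channels), " channels [",
      paste(utils::head(x$channels, 6), collapse = ", "),
      if (length(x$channels) > 6) ", ..." else "", "], ",
      length(x$times_ms), " samples @ ", x$sampling_rate_hz, " Hz (",
      min(x$times_ms), " to ", max(x$times_ms), " ms)\n", sep = "")
  invisible(x)
}

# left / right / midline from a 10-10 channel label (odd digit = left)
channel_hemisphere <- function(channel) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", channel)))
  dplyr::case_when(
    is.na(num) ~ "midline",
    num %% 2 == 1 ~ "left",
    TRUE ~ "right"
  )
}

#' Re-epoch data around per-trial events
#'
#' Cuts a new, shorter epoch out of each trial, re-zeroing the time axis at
#' a per-trial event (typically the interrupter response, at interrupter
#' onset plus reaction time). Trials whose event is missing, or whose new
#' window would run past the edge of the source epoch, are dropped and
#' counted in the `dropped` attribute.
#'
#' @param epochs An [epoch_array()].
#' @param events Tibble with `participant`, `trial`, and `event_ms` (event
#'   time on the source epoch's time axis; NA drops the trial).
#' @param window_ms New window around the event, default -400 to 400 ms.
#' @return An [epoch_array()] whose time axis is `window_ms` re-zeroed at
#'   the event, with attribute `dropped`: a tibble of per-participant
#'   dropped-trial counts.
#' @examples
#' cfg <- task_config(n_participants = 1, n_trials_per_participant = 12)
#' tab <- make_trial_table(cfg)
#' ep <- sample_epochs(tab, cfg, effects = list(), noise_sd = 1, seed = 1)
#' ev <- dplyr::transmute(tab, participant, trial,
#'                        event_ms = onset_ms + interrupter_rt_ms)
#' epoch_around_event(ep, ev)
#' @export
epoch_around_event <- function(epochs, events, window_ms = c(-400, 400)) {
  stopifnot(inherits(epochs, "epoch_array"))
  check_columns(events, c("participant", "trial", "event_ms"))
  fs <- epochs$sampling_rate_hz
  step <- 1000 / fs
  n_out <- round(diff(window_ms) / step) + 1
  new_times <- window_ms[1] + step * (seq_len(n_out) - 1)
  t0 <- epochs$times_ms[1]

  out_data <- vector("list", length(epochs$data))
  out_trials <- vector("list", length(epochs$data))
  dropped <- integer(length(epochs$data))
  for (i in seq_along(epochs$data)) {
    pid <- epochs$participants[i]
    ids <- epochs$trials[[i]]
    ev <- events$event_ms[match(
      paste(pid, ids),
      paste(events$participant, events$trial)
    )]
    start_idx <- round((ev + window_ms[1] - t0) / step) + 1
    keep <- !is.na(ev) & start_idx >= 1 &
      (start_idx + n_out - 1) <= length(epochs$times_ms)
    dropped[i] <- sum(!keep)
    arr <- epochs$data[[i]]
    new_arr <- array(NA_real_,
                     c(sum(keep), length(epochs$channels), n_out))
    ki <- which(keep)
    for (j in seq_along(ki)) {
      sel <- start_idx[ki[j]] + seq_len(n_out) - 1
      new_arr[j, , ] <- arr[ki[j], , sel]
    }
    out_data[[i]] <- new_arr
    out_trials[[i]] <- ids[keep]
  }
  out <- epoch_array(out_data, out_trials, epochs$channels, new_times, fs,
                     epochs$participants)
  attr(out, "dropped") <- tibble::tibble(
    participant = epochs$participants, n_dropped = dropped
  )
  out
}
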