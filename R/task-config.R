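#' Configure the simulated retro-cue interruption task
#'
#' Bundles the design constants of the visual-motor working-memory task that
#' the synthetic-data generators emulate: two lateralized tilted bars are
#' encoded, a retro-cue selects one, and in interruption blocks a perceptual
#' discrimination task appears at one of three onsets during the memory
#' delay before the orientation report is probed.
#'
#' Defaults follow the reference design: interrupter onsets at 600, 1400,
#' and 2400 ms after retro-cue onset, epochs from -200 to 4200 ms around
#' the cue, a 250 Hz sampling rate, and the report probe at 3200 ms.
#'
#' @param n_participants Number of simulated participants.
#' @param n_trials_per_participant Trials per participant. With the default
#'   block structure (1/3 no-interruption, 2/3 interruption split evenly
#'   over three onsets) a multiple of 12 gives an exactly balanced design.
#' @param interrupter_onsets_ms Strictly increasing onset times (ms after
#'   retro-cue) of the interrupting task, labelled early/medium/late.
#' @param epoch_window_ms Length-2 epoch window (ms relative to the cue).
#' @param sampling_rate_hz Sampling rate of simulated traces (Hz).
#' @param probe_time_ms Onset of the working-memory probe (ms post-cue).
#' @param seed Integer seed; together with the config it fully determines
#'   every generated dataset.
#' @return A `task_config` list with the validated fields above.
#' @examples
#' cfg <- task_config(n_participants = 2, n_trials_per_participant = 24)
#' cfg$interrupter_onsets_ms
#' @export
task_config <- function(n_participants = 20,
                        n_trials_per_participant = 648,
                        interrupter_onsets_ms = c(600, 1400, 2400),
                        epoch_window_ms = c(-200, 4200),
                        sampling_rate_hz = 250,
                        probe_time_ms = 3200,
                        seed = 1L) {
  if (length(n_participants) != 1 || n_participants < 1) {
    abort("`n_participants` must be a single positive count.")
  }
  if (length(n_trials_per_participant) != 1 || n_trials_per_participant < 1) {
    abort("`n_trials_per_participant` must be a single positive count.")
  }
  if (is.unsorted(interrupter_onsets_ms, strictly = TRUE)) {
    abort("`interrupter_onsets_ms` must be strictly increasing.")
  }
  if (length(epoch_window_ms) != 2 || diff(epoch_window_ms) <= 0) {
    abort("`epoch_window_ms` must be (start, end) with start < end.")
  }
  if (any(interrupter_onsets_ms <= epoch_window_ms[1]) ||
      any(interrupter_onsets_ms >= epoch_window_ms[2])) {
    abort("Interrupter onsets must lie inside the epoch window.")
  }
  if (sampling_rate_hz <= 0) abort("`sampling_rate_hz` must be positive.")
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_trials_per_participant = as.integer(n_trials_per_participant),
      interrupter_onsets_ms = as.numeric(interrupter_onsets_ms),
      epoch_window_ms = as.numeric(epoch_window_ms),
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      probe_time_ms = as.numeric(probe_time_ms),
      seed = as.integer(seed)
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat("  participants:", x$n_participants,
      " trials/participant:", x$n_trials_per_participant, "\n")
  cat("  interrupter onsets (ms):",
      paste(x$interrupter_onsets_ms, collapse = ", "), "\n")
  cat("  epoch (ms):", x$epoch_window_ms[1], "to", x$epoch_window_ms[2],
      " @", x$sampling_rate_hz, "Hz\n")
  cat("  probe (ms):", x$probe_time_ms, "  seed:", x$seed, "\n")
  invisible(x)
}

# Evaluate expr under a locally-set seed when one is given; otherwise use the
# ambient RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Truncated-normal interrupter reaction times (ms): mean 400, sd 50,
# bounded to the (100, 800) response window. Simple rejection sampling.
sample_interrupter_rt <- function(n, mean = 400, sd = 50,
                                  lower = 100, upper = 800) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower | out[bad] >= upper]
  }
  out
}
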