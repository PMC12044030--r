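#' Simulate fixational gaze traces with a bias toward the cued item
#'
#' Generates binocular gaze position time series (degrees visual angle,
#' fixation at 0) for every trial of a trial table. The horizontal trace
#' contains two deflections signed by the cued side — one locked to the
#' retro-cue and, on interruption trials, one locked to the interrupter
#' response — each a Gaussian bump of peak amplitude `towardness_amp`, so
#' the group towardness time course recovers `towardness_amp` at the bump
#' peaks. Smooth low-pass noise is added to both axes and to each eye
#' independently, and optional blink artifacts saturate both axes to a
#' large off-scale value for their duration.
#'
#' @param table Trial table (needs `participant`, `trial`, `cued_side`,
#'   `onset_ms`, `interrupter_rt_ms`).
#' @param cfg A [task_config()]; sets the epoch window.
#' @param towardness_amp Peak amplitude (degrees) of the gaze bias toward
#'   the cued item. Keep well below the 2.75-degree fixation criterion so
#'   trials survive preprocessing.
#' @param blink_rate Blink artifacts per second (Poisson); 0 disables.
#' @param noise_sd Standard deviation (degrees) of the smooth noise.
#' @param raw_rate_hz Sampling rate of the generated raw traces (the
#'   preprocessing chain downsamples to 250 Hz).
#' @param blink_duration_ms Range of blink artifact durations.
#' @param seed Optional integer seed for this step alone.
#' @return A list of class `gaze_raw` with `samples` (tibble: `participant`,
#'   `trial`, `time_ms`, `x_left`, `y_left`, `x_right`, `y_right`) and
#'   `blinks` (tibble of ground-truth artifact intervals: `participant`,
#'   `trial`, `start_ms`, `end_ms`), plus the raw sampling rate.
#' @examples
#' cfg <- task_config(n_participants = 1, n_trials_per_participant = 8)
#' gz <- sample_gaze(make_trial_table(cfg), cfg, towardness_amp = 0.1,
#'                   raw_rate_hz = 250, seed = 1)
#' head(gz$samples)
#' @export
sample_gaze <- function(table, cfg,
                        towardness_amp = 0.1,
                        blink_rate = 0,
                        noise_sd = 0.25,
                        raw_rate_hz = 1000,
                        blink_duration_ms = c(100, 300),
                        seed = NULL) {
  stopifnot(inherits(cfg, "task_config"))
  check_columns(table, c("participant", "trial", "cued_side", "onset_ms",
                         "interrupter_rt_ms"))
  if (raw_rate_hz < 250) abort("`raw_rate_hz` must be at least 250 Hz.")
  t_ms <- seq(cfg$epoch_window_ms[1], cfg$epoch_window_ms[2],
              by = 1000 / raw_rate_hz)
  ns <- length(t_ms)
  epoch_s <- diff(cfg$epoch_window_ms) / 1000

  with_seed_if(seed, {
    blink_list <- list()
    samples <- purrr::map_dfr(seq_len(nrow(table)), function(i) {
      side_sign <- if (table$cued_side[i] == "right") 1 else -1
      x <- side_sign * towardness_amp * gauss_bump(t_ms, 400, 200)
      if (!is.na(table$onset_ms[i]) && !is.na(table$interrupter_rt_ms[i])) {
        resp <- table$onset_ms[i] + table$interrupter_rt_ms[i]
        x <- x + side_sign * towardness_amp * gauss_bump(t_ms, resp + 150, 200)
      }
      common_x <- x + smooth_noise(ns, noise_sd)
      common_y <- smooth_noise(ns, noise_sd)
      x_l <- common_x + smooth_noise(ns, noise_sd / 4)
      x_r <- common_x + smooth_noise(ns, noise_sd / 4)
      y_l <- common_y + smooth_noise(ns, noise_sd / 4)
      y_r <- common_y + smooth_noise(ns, noise_sd / 4)
      if (blink_rate > 0) {
        n_blinks <- stats::rpois(1, blink_rate * epoch_s)
        if (n_blinks > 0) {
          dur <- runif(n_blinks, blink_duration_ms[1], blink_duration_ms[2])
          start <- runif(n_blinks, t_ms[1], t_ms[ns] - dur)
          for (b in seq_len(n_blinks)) {
            sel <- t_ms >= start[b] & t_ms <= start[b] + dur[b]
            x_l[sel] <- 15; x_r[sel] <- 15
            y_l[sel] <- -15; y_r[sel] <- -15
          }
          blink_list[[length(blink_list) + 1]] <<- tibble::tibble(
            participant = table$participant[i], trial = table$trial[i],
            start_ms = start, end_ms = start + dur
          )
        }
      }
      tibble::tibble(
        participant = table$participant[i], trial = table$trial[i],
        time_ms = t_ms, x_left = x_l, y_left = y_l,
        x_right = x_r, y_right = y_r
      )
    })
    blinks <- if (length(blink_list)) dplyr::bind_rows(blink_list) else
      tibble::tibble(participant = integer(), trial = integer(),
                     start_ms = double(), end_ms = double())
    structure(list(samples = samples, blinks = blinks,
                   sampling_rate_hz = raw_rate_hz),
              class = "gaze_raw")
  })
}

gauss_bump <- function(t, centre, sd) exp(-(t - centre)^2 / (2 * sd^2))

# Gaussian noise low-passed with a moving average, rescaled to sd `sd`:
# gives slow fixational drift rather than white jitter.
smooth_noise <- function(n, sd, width = 51) {
  if (sd <= 0) return(numeric(n))
  raw <- rnorm(n + width)
  sm <- stats::filter(raw, rep(1 / width, width), sides = 2)
  sm <- sm[!is.na(sm)][seq_len(n)]
  sd * sm / stats::sd(sm)
}

#' Simulate paired visual and motor reselection time courses
#'
#' Generates, for each simulated participant, the pair of band-lateralization
#' time courses that the response-locked analysis produces: a transient
#' negative-going visual (alpha) course and a motor (beta) course that can
#' be delayed by a known amount, both with additive smooth noise. This is
#' the desk-scale ground truth for the cross-correlation lag machinery.
#'
#' @param n_participants Number of simulated participants.
#' @param window_ms Time window (ms relative to the interrupter response).
#' @param sampling_rate_hz Sampling rate of the courses.
#' @param motor_delay_ms Planted delay of the motor course relative to the
#'   visual course (positive = motor later).
#' @param amplitude Peak magnitude of the (negative) deflections.
#' @param noise_sd Noise standard deviation, same units as `amplitude`.
#' @param sustained If `TRUE` the motor course stays attenuated to the end
#'   of the window instead of returning to baseline.
#' @param seed Optional integer seed.
#' @return Tibble: `participant`, `time_ms`, `visual`, `motor`.
#' @examples
#' crs <- sample_reselection_courses(5, motor_delay_ms = 100, seed = 1)
#' @export
sample_reselection_courses <- function(n_participants = 30,
                                       window_ms = c(-400, 400),
                                       sampling_rate_hz = 250,
                                       motor_delay_ms = 0,
                                       amplitude = 10,
                                       noise_sd = 0.5,
                                       sustained = FALSE,
                                       seed = NULL) {
  t_ms <- seq(window_ms[1], window_ms[2], by = 1000 / sampling_rate_hz)
  ns <- length(t_ms)
  with_seed_if(seed, {
    purrr::map_dfr(seq_len(n_participants), function(pp) {
      # deflection centres sit well inside the window (no edge truncation)
      # and the 50-ms width keeps the cross-correlation peak sharp enough
      # that the partial-overlap baseline term cannot displace it
      vis <- -amplitude * gauss_bump(t_ms, 100, 50)
      if (sustained) {
        motor_shape <- -amplitude *
          pmin(1, pmax(0, (t_ms - motor_delay_ms) / 150))
      } else {
        motor_shape <- -amplitude * gauss_bump(t_ms, 100 + motor_delay_ms, 50)
      }
      tibble::tibble(
        participant = pp, time_ms = t_ms,
        visual = vis + smooth_noise(ns, noise_sd, width = 15),
        motor = motor_shape + smooth_noise(ns, noise_sd, width = 15)
      )
    })
  })
}
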