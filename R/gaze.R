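#' Interpolate blink artifacts in a gaze trace
#'
#' Linearly interpolates each blink interval, padded by `pad_ms` on both
#' sides (blinks corrupt the samples around the detected gap as the eyelid
#' closes and reopens). Intervals touching the trace boundary are replaced
#' by the nearest uncorrupted value.
#'
#' @param trace Numeric vector of gaze positions.
#' @param time_ms Time axis of `trace` (ms).
#' @param blink_intervals Tibble/data frame with `start_ms`, `end_ms`.
#' @param pad_ms Padding around each interval (default 100 ms).
#' @return `trace` with the padded intervals interpolated.
#' @examples
#' tr <- seq(0, 1, length.out = 101); tr[40:50] <- 99
#' out <- interpolate_blinks(tr, seq(0, 400, 4),
#'                           data.frame(start_ms = 156, end_ms = 196))
#' @export
interpolate_blinks <- function(trace, time_ms, blink_intervals,
                               pad_ms = 100) {
  check_columns(blink_intervals, c("start_ms", "end_ms"))
  if (!nrow(blink_intervals)) return(trace)
  n <- length(trace)
  bad <- rep(FALSE, n)
  for (k in seq_len(nrow(blink_intervals))) {
    bad <- bad | (time_ms >= blink_intervals$start_ms[k] - pad_ms &
                    time_ms <= blink_intervals$end_ms[k] + pad_ms)
  }
  if (!any(bad)) return(trace)
  if (all(bad)) abort("Blink intervals cover the whole trace.")
  good <- which(!bad)
  out <- trace
  out[bad] <- stats::approx(time_ms[good], trace[good], xout = time_ms[bad],
                            rule = 2)$y  # rule 2: nearest value at edges
  out
}

#' Detect saturated (blink-like) segments in a gaze trace
#'
#' Simple saturation detector for external data without blink annotations:
#' samples whose absolute position exceeds `threshold_deg` are treated as
#' artifactual and merged into intervals.
#'
#' @param trace Numeric gaze positions (degrees).
#' @param time_ms Time axis (ms).
#' @param threshold_deg Saturation threshold (degrees).
#' @return Tibble with `start_ms`, `end_ms` (possibly zero rows).
#' @export
detect_blinks <- function(trace, time_ms, threshold_deg = 10) {
  bad <- abs(trace) > threshold_deg
  if (!any(bad)) {
    return(tibble::tibble(start_ms = double(), end_ms = double()))
  }
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(start_ms = time_ms[starts[keep]],
                 end_ms = time_ms[ends[keep]])
}

#' Preprocess raw gaze recordings into analysis-ready epochs
#'
#' Runs the fixational-gaze preprocessing chain on a [sample_gaze()] object
#' (or an equivalent list of `samples`/`blinks` tibbles): interpolates
#' blinks (±100 ms padding), averages the two eyes, downsamples to
#' `target_rate_hz` (moving-average anti-aliasing then decimation), epochs
#' to `epoch_window_ms`, removes trials whose horizontal or vertical
#' excursion exceeds `fixation_limit_deg`, smooths with a centred
#' `smooth_samples`-point moving average (edges truncated), and subtracts
#' the pre-cue baseline (mean over `baseline_ms`) per trial. Baselining is
#' applied after smoothing.
#'
#' @param gaze A `gaze_raw` object from [sample_gaze()], or a list with a
#'   `samples` tibble (`participant`, `trial`, `time_ms`, and either
#'   `x_left/x_right/y_left/y_right` or `x`/`y`), optional `blinks`, and
#'   `sampling_rate_hz`.
#' @param target_rate_hz Output sampling rate (default 250 Hz).
#' @param epoch_window_ms Epoch limits (ms relative to the cue).
#' @param fixation_limit_deg Trial-rejection threshold on |x| and |y|.
#' @param smooth_samples Moving-average length at the output rate
#'   (15 samples = 60 ms at 250 Hz).
#' @param baseline_ms Baseline window (ms).
#' @param pad_ms Blink interpolation padding.
#' @return A `gaze_epochs` object: `x`, `y` tibbles (`participant`,
#'   `trial`, `time_ms`, value), `retention` (per-participant kept/total
#'   trial counts; participants whose every trial is removed are reported
#'   there, not dropped silently), `times_ms`, `sampling_rate_hz`.
#' @export
preprocess_gaze <- function(gaze,
                            target_rate_hz = 250,
                            epoch_window_ms = c(-200, 4200),
                            fixation_limit_deg = 2.75,
                            smooth_samples = 15,
                            baseline_ms = c(-200, 0),
                            pad_ms = 100) {
  samples <- tibble::as_tibble(gaze$samples)
  raw_rate <- gaze$sampling_rate_hz %||% 1000
  if (raw_rate < target_rate_hz) {
    abort("Raw sampling rate must be at least the target rate.")
  }
  blinks <- gaze$blinks %||%
    tibble::tibble(participant = integer(), trial = integer(),
                   start_ms = double(), end_ms = double())
  binocular <- all(c("x_left", "x_right") %in% names(samples))
  if (!binocular) check_columns(samples, c("x", "y"))
  dec <- round(raw_rate / target_rate_hz)

  by_trial <- samples |>
    dplyr::group_by(.data$participant, .data$trial) |>
    dplyr::group_map(function(d, key) {
      d <- d[order(d$time_ms), ]
      bl <- blinks[blinks$participant == key$participant &
                     blinks$trial == key$trial, ]
      if (binocular) {
        cols <- c("x_left", "x_right", "y_left", "y_right")
      } else {
        cols <- c("x", "y")
      }
      for (cc in cols) {
        if (nrow(bl)) d[[cc]] <- interpolate_blinks(d[[cc]], d$time_ms, bl,
                                                    pad_ms)
      }
      x <- if (binocular) (d$x_left + d$x_right) / 2 else d$x
      y <- if (binocular) (d$y_left + d$y_right) / 2 else d$y
      # anti-alias with a decimation-length moving average, then decimate
      if (dec > 1) {
        x <- moving_average(x, dec)[seq(1, length(x), by = dec)]
        y <- moving_average(y, dec)[seq(1, length(y), by = dec)]
        t_ms <- d$time_ms[seq(1, nrow(d), by = dec)]
      } else {
        t_ms <- d$time_ms
      }
      keep <- t_ms >= epoch_window_ms[1] & t_ms <= epoch_window_ms[2]
      x <- x[keep]; y <- y[keep]; t_ms <- t_ms[keep]
      fixated <- all(abs(x) <= fixation_limit_deg) &&
        all(abs(y) <= fixation_limit_deg)
      if (fixated) {
        x <- moving_average(x, smooth_samples)
        y <- moving_average(y, smooth_samples)
        base <- t_ms >= baseline_ms[1] & t_ms <= baseline_ms[2]
        x <- x - mean(x[base])
        y <- y - mean(y[base])
      }
      tibble::tibble(participant = key$participant, trial = key$trial,
                     time_ms = t_ms, x = x, y = y, kept = fixated)
    }) |>
    dplyr::bind_rows()

  retention <- by_trial |>
    dplyr::distinct(.data$participant, .data$trial, .data$kept) |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(n_trials = dplyr::n(), n_kept = sum(.data$kept),
                     retention = .data$n_kept / .data$n_trials,
                     .groups = "drop")
  if (any(retention$n_kept == 0)) {
    warn(paste("Participant(s) with no retained gaze trials:",
               paste(retention$participant[retention$n_kept == 0],
                     collapse = ", ")))
  }
  kept_tbl <- dplyr::filter(by_trial, .data$kept)
  structure(
    list(
      samples = dplyr::select(kept_tbl, -"kept"),
      retention = retention,
      times_ms = sort(unique(kept_tbl$time_ms)),
      sampling_rate_hz = target_rate_hz
    ),
    class = "gaze_epochs"
  )
}

# centred moving average with edge truncation (shorter windows at the ends)
moving_average <- function(x, width) {
  if (width <= 1) return(x)
  half <- (width - 1) / 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(1, seq_len(n) - floor(half))
  hi <- pmin(n, seq_len(n) + ceiling(half))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' @export
print.gaze_epochs <- function(x, ...) {
  cat("<gaze_epochs> ", nrow(x$retention), " participants, ",
      sum(x$retention$n_kept), "/", sum(x$retention$n_trials),
      " trials retained, ", length(x$times_ms), " samples @ ",
      x$sampling_rate_hz, " Hz\n", sep = "")
  invisible(x)
}

#' Gaze towardness relative to the cued item
#'
#' Collapses left- and right-cued horizontal gaze into a single signed
#' bias: at every time point, towardness = (mean x over right-cued trials
#' minus mean x over left-cued trials) / 2, with positions left of fixation
#' negative. Positive towardness means gaze is biased toward the cued
#' item's location, whichever side it was on.
#'
#' @param gaze_epochs A `gaze_epochs` object from [preprocess_gaze()], or a
#'   tibble with `participant`, `trial`, `time_ms`, `x`.
#' @param table Trial table supplying `cued_side` per (`participant`,
#'   `trial`).
#' @return A `towardness` tibble: `participant`, `time_ms`, `towardness`
#'   (degrees). Supports [autoplot()].
#' @export
towardness <- function(gaze_epochs, table) {
  samples <- if (inherits(gaze_epochs, "gaze_epochs")) gaze_epochs$samples
             else tibble::as_tibble(gaze_epochs)
  check_columns(samples, c("participant", "trial", "time_ms", "x"))
  check_columns(table, c("participant", "trial", "cued_side"))
  joined <- dplyr::inner_join(
    samples,
    dplyr::select(table, "participant", "trial", "cued_side"),
    by = c("participant", "trial")
  )
  counts <- joined |>
    dplyr::distinct(.data$participant, .data$trial, .data$cued_side) |>
    dplyr::count(.data$participant, .data$cued_side)
  if (!all(c("left", "right") %in% counts$cued_side)) {
    abort("Both left- and right-cued trials are required for towardness.")
  }
  out <- joined |>
    dplyr::group_by(.data$participant, .data$time_ms, .data$cued_side) |>
    dplyr::summarise(mx = mean(.data$x), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cued_side", values_from = "mx") |>
    dplyr::mutate(towardness = (.data$right - .data$left) / 2) |>
    dplyr::select("participant", "time_ms", "towardness")
  structure(out, class = c("towardness", class(out)))
}

#' Participant-by-time matrix from a long per-participant time course
#'
#' Reshapes a tidy per-participant time course (towardness, band courses,
#' bias curves) into the participants x points matrix that
#' [cluster_permutation_test()] consumes.
#'
#' @param data Tibble with a participant column, an axis column, and a
#'   value column.
#' @param axis,value Names of the axis and value columns.
#' @return Numeric matrix (participants x axis points) with the axis
#'   values as an `"axis"` attribute.
#' @export
course_matrix <- function(data, axis = "time_ms", value = "towardness") {
  check_columns(data, c("participant", axis, value))
  wide <- data |>
    dplyr::select("participant", dplyr::all_of(c(axis, value))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(axis),
                       values_from = dplyr::all_of(value)) |>
    dplyr::arrange(.data$participant)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$participant
  attr(m, "axis") <- as.numeric(colnames(wide)[-1])
  m
}
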