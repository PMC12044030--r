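#' Morlet time-frequency decomposition with a fixed-duration window
#'
#' Convolves every trial and channel with complex Morlet wavelets over
#' `freqs` and returns power (squared magnitude). The analysis window has a
#' fixed duration (default 300 ms) at every frequency, so the number of
#' cycles scales with frequency (`n_cycles = f * window_ms / 1000`: 3
#' cycles at 10 Hz, 6 at 20 Hz). Each wavelet is a complex sinusoid under a
#' Gaussian envelope whose standard deviation is `window_ms / 1000 / (2*pi)`
#' seconds (so the ±pi-sigma extent of the envelope spans the stated
#' window), mean-corrected for admissibility and L2-normalized.
#'
#' Time points closer than half the window to either epoch edge are
#' flagged invalid (`valid` field); downstream cluster statistics exclude
#' them.
#'
#' @param epochs An [epoch_array()].
#' @param freqs Frequencies in Hz (default 3-40 in 1-Hz steps). Must stay
#'   below the Nyquist frequency.
#' @param window_ms Analysis-window duration (ms).
#' @param channels Optional subset of channels to decompose.
#' @param decim Keep every `decim`-th output sample (power varies slowly,
#'   so cluster statistics are routinely run at reduced time resolution).
#' @return A `tfr` object: per-participant power arrays
#'   (trials x channels x frequencies x times), trial ids, `channels`,
#'   `freqs`, decimated `times_ms`, `valid` flags, and sampling info.
#' @examples
#' cfg <- task_config(n_participants = 1, n_trials_per_participant = 8)
#' tab <- make_trial_table(cfg)
#' ep <- sample_epochs(tab, cfg, list(), seed = 1)
#' tfr <- morlet_tfr(ep, freqs = 8:12, decim = 4)
#' @export
morlet_tfr <- function(epochs, freqs = 3:40, window_ms = 300,
                       channels = NULL, decim = 1) {
  stopifnot(inherits(epochs, "epoch_array"))
  fs <- epochs$sampling_rate_hz
  if (any(freqs <= 0)) abort("Frequencies must be positive.")
  if (is.unsorted(freqs, strictly = TRUE)) {
    abort("`freqs` must be strictly increasing.")
  }
  if (max(freqs) > fs / 2) {
    abort("Frequencies above the Nyquist frequency cannot be resolved.")
  }
  if (is.null(channels)) channels <- epochs$channels
  ch_idx <- match(channels, epochs$channels)
  if (anyNA(ch_idx)) abort("Unknown channel label(s) requested.")
  ns <- length(epochs$times_ms)
  half_win_s <- window_ms / 2000
  if (ns / fs <= 2 * half_win_s) {
    abort("Epoch must be longer than the analysis window.")
  }

  kernels <- purrr::map(freqs, ~ morlet_kernel(.x, fs, window_ms))
  nker <- max(lengths(kernels))
  nfft <- 2^ceiling(log2(ns + nker))
  kern_f <- purrr::map(kernels, function(k) {
    # centre the kernel at sample 1 (wrapping) so convolution is zero-lag
    half <- (length(k) - 1) / 2
    padded <- complex(real = numeric(nfft))
    padded[1:(half + 1)] <- k[(half + 1):length(k)]
    padded[(nfft - half + 1):nfft] <- k[1:half]
    fft(padded)
  })

  keep_t <- seq(1, ns, by = decim)
  out_times <- epochs$times_ms[keep_t]
  edge <- window_ms / 2
  valid <- out_times >= (epochs$times_ms[1] + edge) &
    out_times <= (epochs$times_ms[ns] - edge)

  power <- purrr::map(epochs$data, function(arr) {
    n_tr <- dim(arr)[1]
    flat <- matrix(0, nfft, n_tr * length(ch_idx))
    col <- 0
    for (ci in ch_idx) for (tr in seq_len(n_tr)) {
      col <- col + 1
      flat[1:ns, col] <- arr[tr, ci, ]
    }
    Fsig <- stats::mvfft(flat)
    out <- array(NA_real_, c(n_tr, length(ch_idx), length(freqs),
                             length(keep_t)))
    for (fi in seq_along(freqs)) {
      conv <- stats::mvfft(Fsig * kern_f[[fi]], inverse = TRUE) / nfft
      pw <- Mod(conv[keep_t, , drop = FALSE])^2
      col <- 0
      for (ci in seq_along(ch_idx)) for (tr in seq_len(n_tr)) {
        col <- col + 1
        out[tr, ci, fi, ] <- pw[, col]
      }
    }
    out
  })

  structure(
    list(power = power, trials = epochs$trials, channels = channels,
         freqs = as.numeric(freqs), times_ms = out_times, valid = valid,
         sampling_rate_hz = fs / decim, window_ms = window_ms,
         participants = epochs$participants),
    class = "tfr"
  )
}

# Complex Morlet wavelet at frequency f: Gaussian-envelope sinusoid with
# sigma_t = window_s / (2 pi), zero-mean corrected, unit L2 norm.
morlet_kernel <- function(f, fs, window_ms) {
  sigma_t <- window_ms / 1000 / (2 * pi)
  half <- ceiling(3.5 * sigma_t * fs)
  t <- (-half:half) / fs
  env <- exp(-t^2 / (2 * sigma_t^2))
  w <- env * exp(1i * 2 * pi * f * t)
  w <- w - env * sum(w) / sum(env)   # admissibility: zero mean
  w / sqrt(sum(Mod(w)^2))
}

#' @export
print.tfr <- function(x, ...) {
  cat("<tfr> ", length(x$power), " participants, ", length(x$channels),
      " channels, ", length(x$freqs), " frequencies (",
      min(x$freqs), "-", max(x$freqs), " Hz), ", length(x$times_ms),
      " times @ ", x$sampling_rate_hz, " Hz\n", sep = "")
  invisible(x)
}

#' Hemispheric lateralization index of band power
#'
#' Computes, for a left/right electrode pair, the normalized
#' contra-versus-ipsi power difference `100 * (contra - ipsi) /
#' (contra + ipsi)` per participant, frequency, and time. For each
#' electrode, trials are split by whether the relevant feature (cued item
#' side for `basis = "item_side"`, required response hand for
#' `basis = "response_hand"`) was contralateral or ipsilateral to it;
#' power is averaged over trials within each split before the normalized
#' difference (induced-power convention), and the two electrodes' indices
#' are averaged. Cells with zero total power propagate `NA`, never 0.
#'
#' @param tfr A [morlet_tfr()] result containing both pair channels.
#' @param table Trial table with `participant`, `trial`, `cued_side`,
#'   `response_hand`.
#' @param pair Left/right channel pair (e.g. `c("PO7", "PO8")` for the
#'   visual index, `c("C3", "C4")` for the motor index).
#' @param basis `"item_side"` or `"response_hand"`.
#' @return A `tfr_lateralization` object: `index` array (participants x
#'   frequencies x times, values in [-100, 100]), plus the axes and
#'   `valid` flags inherited from the TFR.
#' @export
lateralization_index <- function(tfr, table,
                                 pair = c("PO7", "PO8"),
                                 basis = c("item_side", "response_hand")) {
  stopifnot(inherits(tfr, "tfr"))
  basis <- match.arg(basis)
  check_columns(table, c("participant", "trial", "cued_side", "response_hand"))
  ch_idx <- match(pair, tfr$channels)
  if (anyNA(ch_idx)) abort("Both pair channels must be present in the TFR.")
  hemi <- channel_hemisphere(pair)
  if (!setequal(hemi, c("left", "right"))) {
    abort("`pair` must contain one left- and one right-hemisphere channel.")
  }
  label_col <- if (basis == "item_side") "cued_side" else "response_hand"

  nf <- length(tfr$freqs); nt <- length(tfr$times_ms)
  np <- length(tfr$power)
  index <- array(NA_real_, c(np, nf, nt))
  for (i in seq_len(np)) {
    ids <- tfr$trials[[i]]
    lab <- table[[label_col]][match(
      paste(tfr$participants[i], ids),
      paste(table$participant, table$trial)
    )]
    if (anyNA(lab)) abort("Every TFR trial must appear in the trial table.")
    per_electrode <- array(NA_real_, c(2, nf, nt))
    for (e in 1:2) {
      contra_lab <- if (hemi[e] == "left") "right" else "left"
      contra <- lab == contra_lab
      if (!any(contra) || all(contra)) {
        abort("Both contra and ipsi trials are required for each electrode.")
      }
      pw <- tfr$power[[i]][, ch_idx[e], , , drop = FALSE]
      cmean <- apply(pw[contra, 1, , , drop = FALSE], c(3, 4), mean)
      imean <- apply(pw[!contra, 1, , , drop = FALSE], c(3, 4), mean)
      denom <- cmean + imean
      li <- 100 * (cmean - imean) / denom
      li[denom == 0] <- NA_real_
      per_electrode[e, , ] <- li
    }
    index[i, , ] <- (per_electrode[1, , ] + per_electrode[2, , ]) / 2
  }
  structure(
    list(index = index, freqs = tfr$freqs, times_ms = tfr$times_ms,
         valid = tfr$valid, pair = pair, basis = basis,
         participants = tfr$participants),
    class = "tfr_lateralization"
  )
}

#' @export
print.tfr_lateralization <- function(x, ...) {
  cat("<tfr_lateralization> ", x$pair[1], "/", x$pair[2], " by ", x$basis,
      ": ", dim(x$index)[1], " participants x ", length(x$freqs),
      " freqs x ", length(x$times_ms), " times\n", sep = "")
  invisible(x)
}

#' Band-averaged lateralization time course
#'
#' Unweighted mean of the lateralization index over the frequencies of a
#' predefined band (alpha 8-12 Hz for the visual index, beta 13-30 Hz for
#' the motor index), per participant and time point.
#'
#' @param lat A [lateralization_index()] result.
#' @param band `c(low, high)` in Hz or `"alpha"` / `"beta"`.
#' @return A `band_course` tibble: `participant`, `time_ms`, `index`,
#'   `valid`; the band is stored as an attribute. Supports [autoplot()].
#' @export
band_course <- function(lat, band = "alpha") {
  stopifnot(inherits(lat, "tfr_lateralization"))
  if (is.character(band)) {
    band <- switch(band, alpha = c(8, 12), beta = c(13, 30),
                   abort("Unknown band name."))
  }
  sel <- lat$freqs >= band[1] & lat$freqs <= band[2]
  if (!any(sel)) abort("Band contains no TFR frequencies.")
  course <- apply(lat$index[, sel, , drop = FALSE], c(1, 3), mean)
  out <- tidyr::expand_grid(participant = lat$participants,
                            time_ms = lat$times_ms) |>
    dplyr::arrange(.data$participant, .data$time_ms)
  out$index <- as.vector(t(course))
  out$valid <- rep(lat$valid, length(lat$participants))
  structure(out, class = c("band_course", class(out)),
            band = band, basis = lat$basis, pair = lat$pair)
}

#' Per-channel lateralized topography contrast
#'
#' For every channel, contrasts band-averaged power between trials where
#' the relevant feature pointed right versus left (`100 * (right - left) /
#' (right + left)`), averaged inside each requested time window — the map
#' that localizes a lateralized effect on the scalp.
#'
#' @param tfr A [morlet_tfr()] result (all channels of interest included).
#' @param table Trial table.
#' @param basis `"item_side"` or `"response_hand"`.
#' @param band `c(low, high)` Hz or `"alpha"` / `"beta"`.
#' @param windows_ms Tibble/data frame with `start_ms`, `end_ms` rows, or
#'   a single `c(start, end)`.
#' @return Tibble: `participant`, `channel`, `start_ms`, `end_ms`,
#'   `index`.
#' @export
topography_contrast <- function(tfr, table,
                                basis = c("item_side", "response_hand"),
                                band = "alpha",
                                windows_ms = c(0, 400)) {
  stopifnot(inherits(tfr, "tfr"))
  basis <- match.arg(basis)
  if (length(tfr$channels) < 2) abort("Need at least 2 channels.")
  if (is.character(band)) {
    band <- switch(band, alpha = c(8, 12), beta = c(13, 30),
                   abort("Unknown band name."))
  }
  if (is.numeric(windows_ms) && is.null(dim(windows_ms))) {
    windows_ms <- tibble::tibble(start_ms = windows_ms[1],
                                 end_ms = windows_ms[2])
  }
  windows_ms <- tibble::as_tibble(windows_ms)
  check_columns(windows_ms, c("start_ms", "end_ms"))
  label_col <- if (basis == "item_side") "cued_side" else "response_hand"
  fsel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  if (!any(fsel)) abort("Band contains no TFR frequencies.")

  purrr::map_dfr(seq_along(tfr$power), function(i) {
    ids <- tfr$trials[[i]]
    lab <- table[[label_col]][match(
      paste(tfr$participants[i], ids),
      paste(table$participant, table$trial)
    )]
    purrr::map_dfr(seq_len(nrow(windows_ms)), function(w) {
      tsel <- tfr$times_ms >= windows_ms$start_ms[w] &
        tfr$times_ms <= windows_ms$end_ms[w]
      pw <- tfr$power[[i]][, , fsel, tsel, drop = FALSE]
      band_pow <- apply(pw, c(1, 2), mean)   # trials x channels
      right <- colMeans(band_pow[lab == "right", , drop = FALSE])
      left <- colMeans(band_pow[lab == "left", , drop = FALSE])
      denom <- right + left
      idx <- 100 * (right - left) / denom
      idx[denom == 0] <- NA_real_
      tibble::tibble(participant = tfr$participants[i],
                     channel = tfr$channels,
                     start_ms = windows_ms$start_ms[w],
                     end_ms = windows_ms$end_ms[w],
                     index = idx)
    })
  })
}
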