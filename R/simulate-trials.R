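#' Simulate the trial table of the retro-cue interruption task
#'
#' Builds a balanced per-trial design table: cued item side and required
#' response hand are orthogonal (counterbalanced within each onset
#' condition), interruption blocks carry one of three interrupter onsets
#' under fixed or variable temporal predictability, and the sign of the
#' target tilt determines the response hand (leftward/anticlockwise tilt is
#' reported with the left hand). When `n_trials_per_participant` is a
#' multiple of 24 the table is organised into 24-trial blocks mirroring the
#' reference design (one third no-interruption blocks, the remainder split
#' evenly between fixed- and variable-onset interruption blocks); otherwise
#' the same proportions are applied at the trial level.
#'
#' Orientation magnitudes are drawn in 1-degree increments between 10 and
#' 80 degrees, avoiding the vertical and horizontal meridians. Interrupter
#' reaction times are truncated-normal (mean 400 ms, sd 50 ms, bounded to
#' the 100-800 ms response window); probe-response times are log-normal.
#'
#' @param cfg A [task_config()].
#' @param interruption_fraction Fraction of trials in interruption blocks
#'   (default 2/3 as in the reference design).
#' @param interrupter_accuracy Probability of a correct, in-time response
#'   to the interrupting task.
#' @return A tibble with one row per trial: `participant`, `trial`,
#'   `block`, `block_type`, `predictability`, `onset_condition`,
#'   `onset_ms`, `cued_side`, `response_hand`, `target_orientation`,
#'   `interrupter_orientation`, `interrupter_rt_ms`, `interrupter_correct`,
#'   `rt_probe_ms`, and `reported_orientation` (NA until filled by
#'   [sample_reports()]).
#' @examples
#' tab <- make_trial_table(task_config(n_participants = 1,
#'                                     n_trials_per_participant = 48))
#' dplyr::count(tab, onset_condition, cued_side, response_hand)
#' @seealso [sample_reports()], [sample_gaze()], [sample_epochs()]
#' @export
make_trial_table <- function(cfg,
                             interruption_fraction = 2 / 3,
                             interrupter_accuracy = 0.95) {
  stopifnot(inherits(cfg, "task_config"))
  if (interruption_fraction < 0 || interruption_fraction > 1) {
    abort("`interruption_fraction` must be in [0, 1].")
  }
  n <- cfg$n_trials_per_participant
  onsets <- cfg$interrupter_onsets_ms
  onset_labels <- onset_condition_labels(length(onsets))

  with_seed_if(cfg$seed, {
    purrr::map_dfr(seq_len(cfg$n_participants), function(pp) {
      des <- participant_design(n, onsets, onset_labels, interruption_fraction)
      n_int <- sum(des$block_type == "interruption")
      des$participant <- pp
      des$trial <- seq_len(n)
      # tilt sign encodes the response hand: anticlockwise (positive) <-> left
      magnitude <- sample(10:80, n, replace = TRUE)
      des$target_orientation <- ifelse(des$response_hand == "left", 1, -1) *
        magnitude
      des$interrupter_orientation <- NA_real_
      des$interrupter_rt_ms <- NA_real_
      des$interrupter_correct <- NA
      if (n_int > 0) {
        int_rows <- which(des$block_type == "interruption")
        # interrupter tilt counterbalanced against the target tilt
        int_sign <- balanced_cells(c("-", "+"), n_int)
        des$interrupter_orientation[int_rows] <-
          ifelse(int_sign == "+", 1, -1) *
          sample(10:80, n_int, replace = TRUE)
        des$interrupter_correct[int_rows] <-
          runif(n_int) < interrupter_accuracy
        des$interrupter_rt_ms[int_rows] <- sample_interrupter_rt(n_int)
        des$interrupter_rt_ms[int_rows][!des$interrupter_correct[int_rows]] <-
          NA_real_
      }
      des$rt_probe_ms <- stats::rlnorm(n, meanlog = log(700), sdlog = 0.25)
      des$reported_orientation <- NA_real_
      des
    }) |>
      dplyr::select(
        "participant", "trial", "block", "block_type", "predictability",
        "onset_condition", "onset_ms", "cued_side", "response_hand",
        "target_orientation", "interrupter_orientation",
        "interrupter_rt_ms", "interrupter_correct", "rt_probe_ms",
        "reported_orientation"
      )
  })
}

onset_condition_labels <- function(k) {
  if (k == 3) c("early", "medium", "late") else paste0("onset", seq_len(k))
}

# One participant's design rows (condition structure + counterbalanced
# side/hand cells), in randomized block or trial order.
participant_design <- function(n, onsets, onset_labels, interruption_fraction) {
  k <- length(onsets)
  if (n %% 24 == 0 && (n / 24) >= 3) {
    n_blocks <- n / 24
    n_noint <- round(n_blocks * (1 - interruption_fraction))
    n_int <- n_blocks - n_noint
    n_fixed <- floor(n_int / 2)
    blocks <- c(
      purrr::map(seq_len(n_noint), ~ block_rows("no-interruption", "none",
                                                "none", NA_real_, 24)),
      purrr::map(seq_len(n_fixed), function(i) {
        j <- 1 + (i - 1) %% k
        block_rows("interruption", "fixed", onset_labels[j], onsets[j], 24)
      }),
      purrr::map(seq_len(n_int - n_fixed), function(i) {
        idx <- balanced_cells(seq_len(k), 24)
        block_rows("interruption", "variable", onset_labels[idx], onsets[idx], 24)
      })
    )
    blocks <- blocks[sample.int(length(blocks))]
    des <- dplyr::bind_rows(blocks, .id = "block")
    des$block <- as.integer(des$block)
  } else {
    n_int <- round(n * interruption_fraction)
    n_noint <- n - n_int
    per_onset <- diff(round(seq(0, n_int, length.out = k + 1)))
    rows <- dplyr::bind_rows(
      block_rows("no-interruption", "none", "none", NA_real_, n_noint),
      purrr::map_dfr(seq_len(k), function(j) {
        pred <- rep(c("fixed", "variable"), length.out = per_onset[j])
        out <- block_rows("interruption", pred, onset_labels[j], onsets[j],
                          per_onset[j])
        out
      })
    )
    des <- rows[sample.int(nrow(rows)), ]
    des$block <- 1L
  }
  # counterbalance side x hand within each onset condition
  des <- des |>
    dplyr::group_by(.data$onset_condition) |>
    dplyr::mutate(cell = balanced_cells(1:4, dplyr::n())) |>
    dplyr::ungroup()
  cells <- expand.grid(cued_side = c("left", "right"),
                       response_hand = c("left", "right"),
                       stringsAsFactors = FALSE)
  des$cued_side <- cells$cued_side[des$cell]
  des$response_hand <- cells$response_hand[des$cell]
  des$cell <- NULL
  des
}

block_rows <- function(block_type, predictability, onset_condition,
                       onset_ms, n) {
  if (n == 0) {
    return(tibble::tibble(block_type = character(), predictability = character(),
                          onset_condition = character(), onset_ms = double()))
  }
  tibble::tibble(
    block_type = rep_len(block_type, n),
    predictability = rep_len(predictability, n),
    onset_condition = rep_len(onset_condition, n),
    onset_ms = rep_len(onset_ms, n)
  )
}

# n draws from `levels` that are as balanced as possible: complete shuffled
# blocks of the level set, plus a random subset for the remainder.
balanced_cells <- function(levels, n) {
  k <- length(levels)
  full <- n %/% k
  idx <- c(
    unlist(lapply(seq_len(full), function(i) sample.int(k))),
    sample.int(k)[seq_len(n %% k)]
  )
  levels[idx]
}
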