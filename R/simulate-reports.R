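#' Simulate continuous orientation reports from a circular mixture
#'
#' Fills `reported_orientation` with draws from the three-component mixture
#' that underlies continuous-report behavior: with probability `p_target`
#' the report is a circular-normal (von Mises on doubled angles) draw around
#' the target orientation, optionally shifted toward the interrupter
#' orientation by a smooth attractive bias; with probability `p_nontarget`
#' it is centred on the interrupter orientation (a "swap"); with
#' probability `p_guess` it is uniform on the orientation circle.
#'
#' All circular machinery operates on doubled angles because bar tilts are
#' 180-degree periodic: an orientation error of `e` degrees corresponds to
#' `2 e` degrees on the doubled circle, so `kappa` is the von Mises
#' concentration on that doubled circle (report sd of about 10 degrees in
#' orientation space corresponds to `kappa` near 8.2).
#'
#' The attractive bias is modelled as a derivative-of-Gaussian odd function
#' of the signed target-interrupter difference with peak amplitude
#' `bias_gain` degrees (peaking at a difference of `bias_sd` degrees); the
#' report centre is shifted toward the interrupter by that amount. Trials
#' without an interrupter receive no bias, and their nontarget mass is
#' reassigned to guessing.
#'
#' @param table A trial table from [make_trial_table()] (or equivalent,
#'   with `target_orientation` and `interrupter_orientation` columns).
#' @param p_target,p_nontarget,p_guess Mixture proportions; must be
#'   nonnegative and sum to 1 (tolerance 1e-6).
#' @param kappa Von Mises concentration of the circular-normal components
#'   on the doubled-angle circle.
#' @param bias_gain Peak amplitude (degrees) of the attractive bias toward
#'   the interrupter orientation; 0 disables it.
#' @param bias_sd Width (degrees) of the derivative-of-Gaussian bias curve.
#' @param seed Optional integer seed for this step alone.
#' @return `table` with `reported_orientation` filled (degrees, wrapped to
#'   (-90, 90]).
#' @examples
#' cfg <- task_config(n_participants = 1, n_trials_per_participant = 48)
#' tab <- sample_reports(make_trial_table(cfg), seed = 1)
#' mean(orientation_error(tab$reported_orientation, tab$target_orientation))
#' @export
sample_reports <- function(table,
                           p_target = 0.95, p_nontarget = 0.02,
                           p_guess = 0.03, kappa = 8.2,
                           bias_gain = 0, bias_sd = 20,
                           seed = NULL) {
  check_columns(table, c("target_orientation", "interrupter_orientation"))
  p <- c(p_target, p_nontarget, p_guess)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    abort("Mixture proportions must be nonnegative and sum to 1.")
  }
  if (kappa < 0) abort("`kappa` must be nonnegative.")
  n <- nrow(table)

  with_seed_if(seed, {
    has_int <- !is.na(table$interrupter_orientation)
    comp <- character(n)
    u <- runif(n)
    comp[u < p_target] <- "target"
    comp[u >= p_target & u < p_target + p_nontarget] <- "nontarget"
    comp[u >= p_target + p_nontarget] <- "guess"
    comp[comp == "nontarget" & !has_int] <- "guess"

    centre <- table$target_orientation
    if (bias_gain != 0) {
      diff_ti <- rep(0, n)
      diff_ti[has_int] <- orientation_diff(
        table$interrupter_orientation[has_int],
        table$target_orientation[has_int]
      )
      centre <- centre + bias_gain * dog_bias(diff_ti, bias_sd)
    }
    centre[comp == "nontarget"] <-
      table$interrupter_orientation[comp == "nontarget"]

    report <- numeric(n)
    noisy <- comp != "guess"
    # von Mises noise on the doubled circle, halved back to orientation space
    report[noisy] <- centre[noisy] +
      rvonmises_rad(sum(noisy), kappa) * 90 / pi
    report[!noisy] <- runif(sum(!noisy), -90, 90)
    table$reported_orientation <- wrap_orientation(report)
    table
  })
}

# Odd, derivative-of-Gaussian-shaped bias curve normalized to peak 1 at
# x = sd; positive x (interrupter anticlockwise of target) pulls reports
# anticlockwise, i.e. toward the interrupter.
dog_bias <- function(x, sd) {
  (x / sd) * exp(0.5 - x^2 / (2 * sd^2))
}

# Von Mises sampler centred at 0 (radians), Best & Fisher (1979) rejection
# scheme; kappa = 0 degenerates to uniform.
rvonmises_rad <- function(n, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  if (!is.finite(kappa)) return(rep(0, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    kk <- sum(ok)
    if (kk > 0) {
      out[(got + 1):(got + kk)] <- sign(u3[ok] - 0.5) * acos(f[ok])
      got <- got + kk
    }
  }
  out
}

check_columns <- function(table, cols) {
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    abort(paste0("Trial table is missing required column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  invisible(table)
}
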