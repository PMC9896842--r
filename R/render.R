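#' Cardiac waveform with two harmonics
#'
#' Unit-range waveform used by the renderer: a first and second harmonic at
#' the cardiac fundamental with second-harmonic energy fraction `h2`,
#' normalised so the peak-to-trough range over one period is exactly 1. A
#' phase shift rotates the waveform without changing its range or harmonic
#' content.
#'
#' @param t times in seconds.
#' @param period cardiac period in seconds.
#' @param h2 second-harmonic energy fraction in \[0, 1\].
#' @param phase time shift in seconds.
#' @return waveform values, range exactly 1 over a full period.
#' @keywords internal
cardiac_waveform <- function(t, period, h2 = 0.2, phase = 0) {
  c1 <- sqrt(1 - h2); c2 <- sqrt(h2)
  r <- periodic_range(c1, 0, c2, 0, period)
  w <- 2 * pi / period
  (c1 * cos(w * (t - phase)) + c2 * cos(2 * w * (t - phase))) / r
}

# AR(1) series stacked as an n_series x n_steps matrix; innovation sd `sd`,
# stationary initial condition.
ar1_noise <- function(n_series, n_steps, phi, sd) {
  if (sd == 0) return(matrix(0, n_series, n_steps))
  eps <- matrix(stats::rnorm(n_series * n_steps, 0, sd), n_series, n_steps)
  eps[, 1] <- eps[, 1] / sqrt(1 - phi^2)
  if (n_steps > 1) {
    for (j in 2:n_steps) eps[, j] <- phi * eps[, j - 1] + eps[, j]
  }
  eps
}

#' Render a synthetic pulsatile fundus recording
#'
#' Produces the green-channel frame stack for one recording plus its
#' pulse-oximeter beep timestamps. Each pixel's intensity time series is
#'
#' \deqn{I_p(t) = \mathrm{base}_p + \mathrm{drift}(t) - A_p\, w(t) +
#'   \varepsilon_p(t)}
#'
#' where `base` depends on the tissue class, `drift` is a global slow
#' non-periodic component (piecewise linear between cardiac-cycle
#' boundaries, bounded by the preset's `drift_magnitude`, hence exactly
#' representable by the analysis model's linear spline), `w` is the
#' two-harmonic cardiac waveform with unit peak-to-trough range (so the
#' periodic range at pixel `p` equals its truth amplitude `A_p`), and
#' \eqn{\varepsilon_p} is per-pixel AR(1) noise. The pulsatile term is
#' *subtracted*: more blood absorbs more green light, so amplitude renders
#' as an intensity decrease; the analysis amplitude (peak-to-trough) is
#' polarity-free. Non-vessel pixels carry base, drift and noise only.
#'
#' @param truth a `ppg_truth` from [amplitude_field()] covering all vessel
#'   pixels.
#' @param tree the `ppg_segmentation` used to build the truth.
#' @param config a [sim_config()].
#' @param preset single-row preset supplying `harmonic2_fraction`,
#'   `ar_coefficient`, `noise_sd`, `drift_magnitude`.
#' @param seed integer seed.
#' @param phase cardiac phase offset in seconds (default drawn from seed).
#' @return list with `video` (a `ppg_video`) and `timing` (a `ppg_timing`
#'   with beeps at each cycle start).
#' @export
render_frames <- function(truth, tree, config, preset, seed = config$seed,
                          phase = NULL) {
  set.seed(seed)
  nt <- n_frames(config)
  ts <- (seq_len(nt) - 1) / config$frame_rate
  n <- config$image_size
  if (is.null(phase)) phase <- stats::runif(1, 0, config$cardiac_period)

  base <- matrix(config$background_level, n, n)
  base[tree$labels == tree$legend[["disc"]]] <- config$disc_level
  base[tree$labels == tree$legend[["cup"]]] <- config$cup_level
  vessel_mask <- tree$labels %in%
    tree$legend[c("artery", "vein", "other_vessel")]
  base[matrix(vessel_mask, n, n)] <- config$vessel_base_level

  # global slow drift: piecewise linear between cycle boundaries
  knots <- c(0, config$cardiac_period * seq_len(config$n_cycles))
  if (preset$drift_magnitude > 0) {
    kv <- stats::runif(length(knots), -preset$drift_magnitude,
                       preset$drift_magnitude)
    drift <- stats::approx(knots, kv, xout = ts, rule = 2)$y
  } else {
    drift <- rep(0, nt)
  }

  wave <- cardiac_waveform(ts, config$cardiac_period,
                           h2 = preset$harmonic2_fraction, phase = phase)

  fm <- if (preset$noise_sd > 0) {
    ar1_noise(n * n, nt, preset$ar_coefficient, preset$noise_sd)
  } else {
    matrix(0, n * n, nt)
  }
  basev <- as.vector(base)
  for (j in seq_len(nt)) fm[, j] <- fm[, j] + basev + drift[j]
  pix_lin <- (truth$pixels$col - 1L) * n + truth$pixels$row
  fm[pix_lin, ] <- fm[pix_lin, ] - outer(truth$pixels$amplitude, wave)

  video <- new_video(array(fm, dim = c(n, n, nt)), ts)
  timing <- cardiac_timing(knots)
  list(video = video, timing = timing)
}
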