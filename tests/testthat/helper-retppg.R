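# Small-image configuration for fast unit tests: same optics (annulus still
# fits) at a quarter of the pixel count of the default study configuration.
quick_config <- function(...) {
  sim_config(image_size = 200, microns_per_pixel = 12,
             disc_center = c(100, 100), odf_levels = c(0, 20), ...)
}

# Single-row preset with selected fields overridden (e.g. noise_sd = 0).
preset_with <- function(group = "N1_N1", ...) {
  p <- group_presets(group)
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

# Exact generalised least squares with the analytic AR(1) covariance
# (marginal variance sigma^2 / (1 - phi^2), correlation phi^|i-j|). The
# overall scale cancels, so the plain correlation matrix suffices.
gls_oracle <- function(y, X, phi) {
  n <- length(y)
  S <- phi^abs(outer(seq_len(n), seq_len(n), "-"))
  Si <- solve(S)
  drop(solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y))
}

# Two-pass closed-form simple linear regression slope.
ols_slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Dense-grid peak-to-trough range of a two-harmonic waveform.
dense_range_oracle <- function(a1, b1, a2, b2, period = 1, n = 2e5) {
  tt <- seq(0, period, length.out = n)
  w <- 2 * pi / period
  g <- a1 * cos(w * tt) + b1 * sin(w * tt) +
    a2 * cos(2 * w * tt) + b2 * sin(2 * w * tt)
  max(g) - min(g)
}

# Per-eye synthetic observation table shared by a couple of LMM tests.
two_group_table <- function(n_per_group = 8, delta = 1, sd = 0,
                            groups = c("N1_N1", "CRVO_CRVO"), seed = 1) {
  set.seed(seed)
  out <- list()
  for (g in seq_along(groups)) {
    for (i in seq_len(n_per_group)) {
      id <- paste0(groups[g], "_", i)
      out[[length(out) + 1]] <- data.frame(
        eye_id = id, participant_id = id,
        vessel_label = "vein", group_id = groups[g],
        odf = c(0, 20), induced_iop = induced_iop(c(0, 20), 16),
        mean_logamp = (g - 1) * delta + rnorm(2, 0, sd),
        age = 60, sex = "F", poag = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
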