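ts75 <- (0:74) / 25

test_that("harmonic_spec places knots at interior cycle boundaries", {
  spec <- harmonic_spec(1, timestamps = ts75)
  expect_equal(spec$knots, c(1, 2))
  expect_equal(spec$n_harmonics, 2)
  expect_equal(spec$ar_order, 1)
  expect_error(harmonic_spec(0, timestamps = ts75), "period")
  expect_error(harmonic_spec(1, knots = c(2, 1)), "strictly increasing")
})

test_that("a pure noiseless first harmonic is recovered exactly", {
  spec <- harmonic_spec(1, timestamps = ts75)
  y <- 50 + 10 * cos(2 * pi * ts75)
  f <- fit_harmonic(y, ts75, spec)
  expect_equal(f$a1, 10, tolerance = 1e-8)
  expect_equal(f$b1, 0, tolerance = 1e-8)
  expect_equal(f$a2, 0, tolerance = 1e-8)
  expect_equal(f$b2, 0, tolerance = 1e-8)
  expect_equal(f$amplitude, 20, tolerance = 1e-6)
  expect_equal(f$log_amplitude, log(20), tolerance = 1e-6)
  expect_false(f$floored)
})

test_that("noiseless two-harmonic signals over a spline drift are exact", {
  spec <- harmonic_spec(1, timestamps = ts75)
  X <- retppg:::harmonic_design(ts75, spec)
  set.seed(42)
  for (rep in 1:5) {
    beta <- c(stats::runif(4, -5, 5),          # trend: intercept, t, hinges
              stats::runif(4, -6, 6))          # a1, b1, a2, b2
    y <- drop(X %*% beta)
    f <- fit_harmonic(y, ts75, spec)
    truth <- dense_range_oracle(beta[5], beta[6], beta[7], beta[8])
    expect_equal(f$amplitude, truth, tolerance = 1e-6 * max(truth, 1))
    expect_equal(unname(f$coefficients), beta, tolerance = 1e-8)
  }
})

test_that("a constant series floors to zero amplitude", {
  spec <- harmonic_spec(1, timestamps = ts75)
  f <- fit_harmonic(rep(7, 75), ts75, spec)
  expect_true(f$floored)
  expect_equal(f$log_amplitude, log(1e-3))
})

test_that("fixed-phi fitting equals the exact AR(1) GLS oracle", {
  n <- 50
  tt <- (seq_len(n) - 1) / 25
  spec <- harmonic_spec(1, timestamps = tt)
  X <- retppg:::harmonic_design(tt, spec)
  set.seed(11)
  for (phi in c(-0.4, 0.2, 0.7)) {
    y <- drop(X %*% stats::rnorm(ncol(X), 0, 3)) +
      as.numeric(retppg:::ar1_noise(1, n, phi, 1))
    f <- fit_harmonic(y, tt, spec, phi = phi)
    expect_equal(unname(f$coefficients), unname(gls_oracle(y, X, phi)),
                 tolerance = 1e-8)
    expect_equal(f$phi, phi)
  }
})

test_that("iterated phi estimation recovers strong autocorrelation", {
  spec <- harmonic_spec(1, timestamps = ts75)
  y0 <- 100 - 8 * cos(2 * pi * ts75)
  set.seed(3)
  phis <- replicate(40, {
    y <- y0 + as.numeric(retppg:::ar1_noise(1, 75, 0.5, 0.5))
    fit_harmonic(y, ts75, spec)$phi
  })
  # Cochrane-Orcutt phi from 75 regression residuals is biased low; require
  # the average to land in a broad band around the generating value
  expect_gt(mean(phis), 0.15)
  expect_lt(mean(phis), 0.65)
  expect_true(all(abs(phis) < 0.99))
})

test_that("coefficient estimates are unbiased within Monte Carlo error", {
  spec <- harmonic_spec(1, timestamps = ts75)
  set.seed(8)
  nrep <- 150
  est <- t(replicate(nrep, {
    y <- 100 + 6 * cos(2 * pi * ts75) + 8 * sin(2 * pi * ts75) +
      2 * cos(4 * pi * ts75) + as.numeric(retppg:::ar1_noise(1, 75, 0.5, 1))
    f <- fit_harmonic(y, ts75, spec)
    c(f$a1, f$b1, f$a2, f$b2)
  }))
  truth <- c(6, 8, 2, 0)
  for (j in 1:4) {
    se <- stats::sd(est[, j]) / sqrt(nrep)
    expect_lt(abs(mean(est[, j]) - truth[j]), 4 * se + 1e-3)
  }
})

test_that("nominal 95% coefficient intervals have near-nominal coverage", {
  spec <- harmonic_spec(1, timestamps = ts75)
  set.seed(12)
  nrep <- 200
  cover_one <- function(phi_arg) {
    y <- 100 + 6 * cos(2 * pi * ts75) +
      as.numeric(retppg:::ar1_noise(1, 75, 0.4, 0.8))
    f <- fit_harmonic(y, ts75, spec, phi = phi_arg)
    se <- sqrt(f$vcov["a1", "a1"])
    abs(f$a1 - 6) <= stats::qnorm(0.975) * se
  }
  # known phi: whitening is exact, so coverage is nominal
  covered <- replicate(nrep, cover_one(0.4))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
  # estimated phi: the Cochrane-Orcutt autocorrelation estimate from short
  # residual series is biased low, which understates the SEs somewhat
  covered_est <- replicate(nrep, cover_one(NULL))
  expect_gte(mean(covered_est), 0.80)
})

test_that("too-sparse sampling and rank deficiency are rejected", {
  tt <- (0:14) / 5   # 5 samples per 1-s cycle
  spec <- harmonic_spec(1, timestamps = tt)
  expect_error(fit_harmonic(stats::rnorm(15), tt, spec), "fewer than 8")
  spec2 <- harmonic_spec(1, knots = seq(0.01, 2.9, by = 0.01))
  expect_error(fit_harmonic(stats::rnorm(75), ts75, spec2),
               "rank-deficient")
})

test_that("peak-to-trough amplitude matches the dense-grid oracle", {
  cases <- list(c(10, 0, 0, 0), c(0, 0, 3, 4), c(6, 8, 2, 0),
                c(-2, 5, 1.5, -3), c(1e-3, 0, 0, 2e-3))
  for (cs in cases) {
    expect_equal(retppg:::periodic_range(cs[1], cs[2], cs[3], cs[4], 1),
                 dense_range_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-7)
  }
  # first-harmonic alternative: twice the harmonic magnitude
  spec <- harmonic_spec(1, timestamps = ts75)
  y <- 10 + 3 * cos(2 * pi * ts75) + 4 * sin(2 * pi * ts75)
  f <- fit_harmonic(y, ts75, spec, amplitude_method = "first_harmonic")
  expect_equal(f$amplitude, 10, tolerance = 1e-6)
})

test_that("log_amplitude floors small values and rejects negatives", {
  expect_equal(as.numeric(log_amplitude(exp(2))), 2)
  expect_equal(as.numeric(log_amplitude(1)), 0)
  la <- log_amplitude(0)
  expect_equal(as.numeric(la), log(1e-3))
  expect_true(attr(la, "floored"))
  expect_error(log_amplitude(-1), ">= 0")
  # monotone above the floor
  x <- c(0.01, 0.1, 1, 10)
  expect_true(all(diff(as.numeric(log_amplitude(x))) > 0))
})

test_that("amplitude bias correction vanishes for noiseless series and shrinks noisy-range inflation", {
  spec <- harmonic_spec(1, timestamps = ts75)
  y <- 50 + 5 * cos(2 * pi * ts75) + 1.5 * cos(4 * pi * ts75)
  f_on <- fit_harmonic(y, ts75, spec)
  f_off <- fit_harmonic(y, ts75, spec, bias_correct = FALSE)
  expect_equal(f_on$amplitude, f_off$amplitude, tolerance = 1e-9)
  # under noise the corrected amplitude is smaller and nearer the truth
  set.seed(31)
  amps <- t(replicate(120, {
    yy <- y + as.numeric(retppg:::ar1_noise(1, 75, 0.5, 0.22))
    c(on = fit_harmonic(yy, ts75, spec)$amplitude,
      off = fit_harmonic(yy, ts75, spec, bias_correct = FALSE)$amplitude)
  }))
  truth <- dense_range_oracle(5, 0, 1.5, 0)
  expect_true(all(amps[, "on"] <= amps[, "off"]))
  expect_lt(abs(mean(amps[, "on"]) - truth),
            abs(mean(amps[, "off"]) - truth))
})
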