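test_that("noiseless vessel pixels pulse with their truth amplitude", {
  cfg <- quick_config()
  tree <- make_vessel_tree(cfg, seed = 4)
  p <- preset_with(noise_sd = 0, drift_magnitude = 0)
  tr <- amplitude_field(p, tree)
  rec <- render_frames(tr, tree, cfg, p, seed = 21)
  fm <- rec$video$frames
  idx <- sample(nrow(tr$pixels), 20)
  for (i in idx) {
    series <- fm[tr$pixels$row[i], tr$pixels$col[i], ]
    obs <- max(series) - min(series)
    # sampled peak-to-trough: within the frame-grid discretisation of the
    # continuous unit-range waveform (25 samples per cycle)
    expect_lt(abs(obs - tr$pixels$amplitude[i]) / tr$pixels$amplitude[i],
              0.02)
    expect_gte(tr$pixels$amplitude[i] + 1e-9, obs)
  }
})

test_that("noiseless spectrum has energy only at DC and the two harmonics", {
  cfg <- quick_config()
  tree <- make_vessel_tree(cfg, seed = 4)
  p <- preset_with(noise_sd = 0, drift_magnitude = 0)
  tr <- amplitude_field(p, tree)
  rec <- render_frames(tr, tree, cfg, p, seed = 21)
  series <- rec$video$frames[tr$pixels$row[1], tr$pixels$col[1], ]
  sp <- Mod(stats::fft(series))^2
  nt <- length(series)                       # 75 frames, 3 cycles
  k <- cfg$n_cycles
  allowed <- c(1, 1 + k, 1 + 2 * k, nt + 1 - k, nt + 1 - 2 * k)
  leak <- sum(sp[-allowed]) / sum(sp)
  expect_lt(leak, 1e-20)
})

test_that("beeps mark cycle starts at the exact cardiac period", {
  cfg <- quick_config()
  tree <- make_vessel_tree(cfg, seed = 4)
  p <- group_presets("N1_N1")
  tr <- amplitude_field(p, tree)
  rec <- render_frames(tr, tree, cfg, p, seed = 8)
  beeps <- rec$timing$beep_times
  expect_length(beeps, cfg$n_cycles + 1)
  expect_equal(diff(beeps), rep(cfg$cardiac_period, cfg$n_cycles))
  expect_equal(estimate_period(rec$timing), cfg$cardiac_period)
})

test_that("rendering is deterministic in the seed", {
  cfg <- quick_config()
  tree <- make_vessel_tree(cfg, seed = 4)
  p <- group_presets("N1_N1")
  tr <- amplitude_field(p, tree)
  r1 <- render_frames(tr, tree, cfg, p, seed = 33)
  r2 <- render_frames(tr, tree, cfg, p, seed = 33)
  r3 <- render_frames(tr, tree, cfg, p, seed = 34)
  expect_identical(r1$video$frames, r2$video$frames)
  expect_false(identical(r1$video$frames, r3$video$frames))
})

test_that("AR(1) noise generator matches its nominal autocorrelation", {
  set.seed(99)
  x <- retppg:::ar1_noise(1, 5000, 0.5, 1)[1, ]
  r1 <- stats::cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.5), 3 / sqrt(length(x)) * (1 - 0.5^2) * 2)
  # stationary marginal variance sigma^2 / (1 - phi^2)
  expect_lt(abs(stats::var(x) - 1 / (1 - 0.25)), 0.1)
  expect_identical(retppg:::ar1_noise(3, 10, 0.5, 0),
                   matrix(0, 3, 10))
})

test_that("cardiac waveform has unit peak-to-trough range", {
  tt <- seq(0, 1, length.out = 1e5)
  for (h2 in c(0, 0.2, 0.5, 1)) {
    w <- retppg:::cardiac_waveform(tt, 1, h2 = h2, phase = 0.17)
    expect_equal(max(w) - min(w), 1, tolerance = 1e-6)
  }
})
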