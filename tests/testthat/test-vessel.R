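test_that("induced IOP follows the printed conversion", {
  expect_equal(induced_iop(50, 10), 54.5)
  expect_equal(induced_iop(0, 15), 15)
  # affine in ODF: constant increment per unit of force
  for (b in c(10, 15, 21)) {
    inc <- diff(induced_iop(0:60, b))
    expect_equal(inc, rep(inc[1], 60), tolerance = 1e-12)
  }
  expect_error(induced_iop(-1, 15), "ODF")
})

test_that("ODF records carry the force conversion", {
  r <- odf_record(20, 16)
  expect_equal(r$odf, 20)
  expect_equal(r$baseline_iop, 16)
  expect_equal(r$induced_iop, induced_iop(20, 16))
  expect_equal(r$grams_force, 3.33 * 20)
})

test_that("amplitude slope equals the closed-form OLS oracle", {
  expect_equal(amplitude_slope(c(0.25, 0.5, 0.75, 1), c(2, 1.8, 1.6, 1.4),
                               min_loci = 4)$slope, -0.8, tolerance = 1e-12)
  set.seed(9)
  for (i in 1:5) {
    d <- stats::runif(30, 0.25, 1)
    la <- 2 - 0.6 * d + stats::rnorm(30, 0, 0.2)
    sl <- amplitude_slope(d, la)
    expect_equal(sl$slope, ols_slope_oracle(d, la), tolerance = 1e-10)
    fit <- stats::lm(la ~ d)
    expect_equal(sl$se, summary(fit)$coefficients["d", "Std. Error"],
                 tolerance = 1e-10)
    expect_equal(sl$intercept, unname(stats::coef(fit)[1]), tolerance = 1e-10)
  }
})

test_that("degenerate slope inputs return NA", {
  expect_true(is.na(amplitude_slope(rep(0.5, 6), stats::rnorm(6))$slope))
  expect_true(is.na(amplitude_slope(c(0.3, 0.4, 0.5), c(1, 2, 3))$slope))
  # span below the minimum is degenerate even with many loci
  expect_true(is.na(amplitude_slope(seq(0.5, 0.6, length.out = 10),
                                    stats::rnorm(10))$slope))
})

test_that("vessel summaries compute mean, max and locus count", {
  m <- structure(data.frame(center_row = 1:6, center_col = 1,
                            vessel_id = c(1, 1, 1, 1, 1, 1), label = "vein",
                            hemifield = "superior",
                            d_mm = seq(0.3, 0.9, length.out = 6),
                            angle_deg = 45,
                            amplitude = exp(c(1, 2, 3, 1, 2, 3)),
                            log_amplitude = c(1, 2, 3, 1, 2, 3)),
                 class = c("amplitude_map", "data.frame"))
  obs <- summarize_vessel(m, 1, odf_record(0, 16), min_loci = 5)
  expect_equal(obs$mean_logamp, 2)
  expect_equal(obs$max_logamp, 3)
  expect_equal(obs$n_loci, 6)
  expect_equal(obs$vessel_label, "vein")
  expect_equal(obs$induced_iop, 16)
})

test_that("vessels with no retained loci are skipped with a message", {
  m <- structure(data.frame(center_row = 1, center_col = 1, vessel_id = 2,
                            label = "vein", hemifield = "superior",
                            d_mm = 0.5, angle_deg = 45, amplitude = 3,
                            log_amplitude = log(3)),
                 class = c("amplitude_map", "data.frame"))
  expect_message(out <- summarize_vessel(m, 99, odf_record(0, 16)),
                 "skipped")
  expect_null(out)
})

test_that("observation tables round-trip through CSV", {
  m <- structure(data.frame(center_row = 1:6, center_col = 1, vessel_id = 1,
                            label = "vein", hemifield = "superior",
                            d_mm = seq(0.3, 0.9, length.out = 6),
                            angle_deg = 45, amplitude = exp(1),
                            log_amplitude = 1 + 0.1 * (1:6)),
                 class = c("amplitude_map", "data.frame"))
  obs <- summarize_vessels(m, odf_record(20, 16), eye_id = "e1",
                           participant_id = "p1",
                           group_by_hemifield = "N1_N1")
  path <- file.path(tempdir(), "obs.csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(back$mean_logamp, obs$mean_logamp)
  expect_equal(back$group_id, obs$group_id)
  expect_equal(back$odf, obs$odf)
  file.remove(path)
})
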