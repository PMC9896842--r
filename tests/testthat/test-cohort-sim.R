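test_that("derived sub-seeds are deterministic and within integer range", {
  s1 <- derive_seeds(1, 10)
  s2 <- derive_seeds(1, 10)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 < .Machine$integer.max))
  expect_false(identical(s1, derive_seeds(2, 10)))
})

test_that("eye plans pair the two HVO hemifield groups on shared eyes", {
  plan <- make_eye_plan(group_presets(), n_eyes_per_group = 1, seed = 3)
  # six groups, but HVO_HVO and N2_HVO live on the same physical eyes
  expect_equal(nrow(plan), 5)
  hvo <- plan[plan$superior_group != plan$inferior_group, ]
  expect_equal(nrow(hvo), 1)
  expect_setequal(unlist(hvo[, c("superior_group", "inferior_group")]),
                  c("HVO_HVO", "N2_HVO"))
  plan4 <- make_eye_plan(group_presets(), n_eyes_per_group = 4, seed = 3)
  expect_equal(nrow(plan4), 20)
  # the affected hemifield is randomised, not fixed
  hvo4 <- plan4[plan4$superior_group != plan4$inferior_group, ]
  expect_equal(nrow(hvo4), 4)
  expect_error(make_eye_plan(group_presets(), 0, seed = 1), ">= 1")
})

test_that("plans without HVO pairing give one eye per group", {
  plan <- make_eye_plan(group_presets(c("N1_N1", "CRVO_CRVO")),
                        n_eyes_per_group = 3, seed = 2)
  expect_equal(nrow(plan), 6)
  expect_true(all(plan$superior_group == plan$inferior_group))
})

test_that("simulate_eye is deterministic and rejects unknown groups", {
  cfg <- quick_config()
  e1 <- simulate_eye("N1_N1", config = cfg, seed = 5)
  e2 <- simulate_eye("N1_N1", config = cfg, seed = 5)
  expect_identical(e1$recordings[[1]]$video$frames,
                   e2$recordings[[1]]$video$frames)
  expect_identical(e1$eye$age, e2$eye$age)
  expect_error(simulate_eye("NOPE", config = cfg, seed = 5),
               "unknown group_id")
})

test_that("eye covariates come from the demographic preset", {
  cfg <- quick_config()
  set.seed(404)
  ages <- vapply(1:8, function(i) {
    simulate_eye("N1_N1", config = cfg, seed = 100 + i)$eye$age
  }, numeric(1))
  p <- group_presets("N1_N1")
  expect_lt(abs(mean(ages) - p$age_mean), 4 * p$age_sd / sqrt(8) + 1)
})

test_that("per-eye truth means scatter with the between-eye dispersion", {
  cfg <- quick_config()
  p <- group_presets("N1_N1")
  offs <- vapply(1:20, function(i) {
    simulate_eye("N1_N1", config = cfg, seed = 2000 + i)$eye$eye_offset
  }, numeric(1))
  sd_hat <- stats::sd(offs)
  # sd of an SD from 20 normal draws: roughly sd / sqrt(2 * 19)
  expect_lt(abs(sd_hat - p$between_eye_sd),
            4 * p$between_eye_sd / sqrt(2 * 19))
  expect_lt(abs(mean(offs)), 4 * p$between_eye_sd / sqrt(20))
})

test_that("simulated observation tables have pipeline structure", {
  obs <- simulate_observations(group_presets(c("N1_N1", "CRVO_CRVO")),
                               n_eyes_per_group = 3, seed = 9)
  expect_true(all(c("eye_id", "participant_id", "vessel_label", "group_id",
                    "odf", "induced_iop", "mean_logamp", "max_logamp",
                    "slope", "age", "sex", "poag") %in% names(obs)))
  # 2 groups x 3 eyes x 2 hemifields x 2 vessel types x 3 ODF levels
  expect_equal(nrow(obs), 2 * 3 * 2 * 2 * 3)
  expect_identical(obs,
                   simulate_observations(group_presets(c("N1_N1", "CRVO_CRVO")),
                                         n_eyes_per_group = 3, seed = 9))
})

test_that("a cohort on disk round-trips through the readers", {
  cfg <- quick_config()
  cfg$odf_levels <- 0
  cohort <- generate_cohort(group_presets("N1_N1"), n_eyes_per_group = 1,
                            config = cfg, seed = 77)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  eye <- cohort$eyes[[1]]
  ed <- file.path(dir, eye$eye$eye_id)
  seg <- read_segmentation(file.path(ed, "segmentation.png"))
  expect_identical(seg$labels, eye$seg$labels)
  v <- read_stack(file.path(ed, "recording_odf000.tif"))
  expect_equal(dim(v$frames), dim(eye$recordings[[1]]$video$frames))
  # one 16-bit quantisation step, allowing for rare clamped noise tails
  expect_lt(stats::quantile(abs(v$frames - eye$recordings[[1]]$video$frames),
                            0.9999), 255 / 65535)
  tm <- read_timing(file.path(ed, "recording_odf000_beeps.csv"))
  expect_equal(tm$beep_times, eye$recordings[[1]]$timing$beep_times)
  unlink(dir, recursive = TRUE)
})
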