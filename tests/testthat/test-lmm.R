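test_that("a pure fixed shift between groups is estimated exactly", {
  tab <- two_group_table(n_per_group = 6, delta = 1, sd = 0)
  fit <- suppressWarnings(fit_lmm(tab, response = "mean_logamp"))
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "group_idCRVO_CRVO"], 1,
               tolerance = 1e-6)
  # with no residual variation the marginal means are the group means
  mm <- fit$marginal_means
  expect_equal(mm$mean[mm$group_id == "N1_N1"], 0, tolerance = 1e-6)
  expect_equal(mm$mean[mm$group_id == "CRVO_CRVO"], 1, tolerance = 1e-6)
})

test_that("mixed model with noise matches OLS when random variance is nil", {
  tab <- two_group_table(n_per_group = 10, delta = 0.7, sd = 0.2, seed = 4)
  fit <- suppressWarnings(fit_lmm(tab, response = "mean_logamp"))
  tab$group_id <- stats::relevel(factor(tab$group_id), ref = "N1_N1")
  ols <- stats::lm(mean_logamp ~ group_id + induced_iop, data = tab)
  # same data, nested model family: estimates agree closely
  expect_equal(fit$coefficients$estimate[
                 fit$coefficients$term == "group_idCRVO_CRVO"],
               unname(stats::coef(ols)[["group_idCRVO_CRVO"]]),
               tolerance = 0.05)
})

test_that("six groups against a reference yield five contrasts", {
  set.seed(6)
  groups <- group_presets()$group_id
  tabs <- lapply(groups, function(g) {
    t <- two_group_table(n_per_group = 4, delta = 0, sd = 0.3,
                         groups = c(g, g), seed = match(g, groups))
    t[seq_len(nrow(t) / 2), ]
  })
  tab <- do.call(rbind, tabs)
  tab$eye_id <- paste0(tab$group_id, "_", tab$eye_id)
  tab$participant_id <- tab$eye_id
  fit <- suppressWarnings(fit_lmm(tab, response = "mean_logamp",
                                  reference = "N1_N1"))
  ctr <- pairwise_contrasts(fit)
  expect_equal(nrow(ctr), 5)
  expect_true(all(ctr$group_b == "N1_N1"))
  expect_setequal(ctr$group_a, setdiff(groups, "N1_N1"))
  expect_type(ctr$significant, "logical")
})

test_that("Bonferroni correction matches the printed threshold", {
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.03, 3), 0.01)
  expect_error(bonferroni_alpha(0.05, 0), "count")
  expect_error(bonferroni_alpha(1.2, 5), "family_alpha")
})

test_that("simulated observations recover preset group means via the LMM", {
  presets <- group_presets()
  obs <- simulate_observations(presets, n_eyes_per_group = 15, seed = 21)
  fit <- suppressWarnings(fit_lmm(obs, response = "mean_logamp",
                                  vessel_label = "vein"))
  mm <- fit$marginal_means
  for (g in presets$group_id) {
    target <- presets$venous_mean_logamp[presets$group_id == g]
    se <- presets$between_eye_sd[presets$group_id == g] / sqrt(15)
    # covariate adjustment adds estimation noise beyond the group-mean SE
    expect_lt(abs(mm$mean[mm$group_id == g] - target), 4 * se + 0.05)
  }
})

test_that("QQ points match hand-computed plotting positions", {
  q <- qq_points(c(-1, 0, 1))
  expect_equal(q$sample, c(-1, 0, 1))
  expect_equal(q$theoretical, stats::qnorm(c(1, 3, 5) / 6))
  expect_error(qq_points(c(1, 2)), "at least 3")
})

test_that("normal residuals track the QQ identity line", {
  set.seed(13)
  q <- qq_points(stats::rnorm(20000))
  inner <- abs(q$theoretical) < 2
  expect_lt(max(abs(q$sample[inner] - q$theoretical[inner])), 0.1)
})

test_that("constant residuals are flagged degenerate", {
  expect_warning(q <- qq_points(rep(2, 10)), "degenerate|constant")
  expect_true(attr(q, "degenerate"))
})
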