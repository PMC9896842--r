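geo <- structure(list(disc_center = c(200, 200), microns_per_pixel = 6),
                 class = "ppg_geometry")

test_that("polar conversion matches hand-computed examples", {
  expect_equal(to_polar(c(200, 200), geo)$d_mm, 0)
  p <- to_polar(c(150, 200), geo)      # 50 px above centre
  expect_equal(p$d_mm, 50 * 6 / 1000)
  expect_equal(p$angle_deg, 90)
  p <- to_polar(c(200, 300), geo)      # 100 px to the right
  expect_equal(p$d_mm, 0.6)
  expect_equal(p$angle_deg, 0)
  p <- to_polar(c(250, 200), geo)      # below centre: inferior
  expect_equal(p$angle_deg, -90)
  p <- to_polar(c(200, 100), geo)      # left: angle convention gives 180
  expect_equal(p$angle_deg, 180)
})

test_that("polar distance is invariant under translation of the frame", {
  g2 <- structure(list(disc_center = c(57, 311), microns_per_pixel = 6),
                  class = "ppg_geometry")
  set.seed(2)
  px <- cbind(sample(400, 25), sample(400, 25))
  a <- to_polar(px, geo)
  b <- to_polar(cbind(px[, 1] - 143, px[, 2] + 111), g2)
  expect_equal(a$d_mm, b$d_mm, tolerance = 1e-12)
  expect_equal(a$angle_deg, b$angle_deg, tolerance = 1e-12)
})

fake_map <- function(d_mm, vessel_id = seq_along(d_mm), angle = 45,
                     logamp = 1) {
  structure(data.frame(center_row = 1, center_col = 1, vessel_id = vessel_id,
                       label = "vein", d_mm = d_mm,
                       angle_deg = rep_len(angle, length(d_mm)),
                       hemifield = "superior",
                       amplitude = exp(rep_len(logamp, length(d_mm))),
                       log_amplitude = rep_len(logamp, length(d_mm))),
            class = c("amplitude_map", "data.frame"))
}

test_that("annulus filtering uses closed bounds and is idempotent", {
  m <- fake_map(c(0.1, 0.2, 0.25, 0.5, 1.0, 1.2))
  f <- annulus_filter(m)
  expect_equal(f$d_mm, c(0.25, 0.5, 1.0))
  expect_equal(attr(f, "n_removed"), 3)
  f2 <- annulus_filter(f)
  expect_equal(f2$d_mm, f$d_mm)
  expect_equal(attr(f2, "n_removed"), 0)
  expect_error(annulus_filter(m, inner = 1, outer = 0.5), "inner bound")
  expect_equal(annulus_filter(fake_map(c(0.1, 0.5, 1.2)))$d_mm, 0.5)
})

test_that("hemifield split follows the sign of the polar angle", {
  m <- data.frame(angle_deg = c(90, -90, 10, 170, -1), vessel_id = 1:5)
  s <- split_hemifield(m)
  expect_equal(s$hemifield,
               c("superior", "inferior", "superior", "superior", "inferior"))
})

test_that("loci on the horizontal axis inherit their vessel's hemifield", {
  m <- data.frame(angle_deg = c(0, 5, 10), vessel_id = c(7, 7, 7))
  expect_equal(split_hemifield(m)$hemifield, rep("superior", 3))
  m2 <- data.frame(angle_deg = c(180, -175, -170), vessel_id = c(8, 8, 8))
  expect_equal(split_hemifield(m2)$hemifield, rep("inferior", 3))
})

test_that("every locus lands in exactly one hemifield", {
  tree <- make_vessel_tree(quick_config(), seed = 2)
  tr <- amplitude_field(group_presets("N1_N1"), tree)
  expect_true(all(tr$loci$hemifield %in% c("superior", "inferior")))
})
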