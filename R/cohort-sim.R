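#' @title Synthetic cohort generation
#' @description One synthetic "eye" is a vessel tree, a ground-truth
#'   amplitude field (with a per-eye random offset), demographics, and one
#'   rendered recording per ophthalmodynamometric force level. Cohorts stack
#'   eyes across the six study groups. The two HVO hemifield groups share
#'   physical eyes: an HVO eye carries the affected-hemivessel (HVO_HVO)
#'   truth on one hemifield and the unaffected-hemivessel (N2_HVO) truth on
#'   the other, with the affected side randomised per eye.
#' @name cohort-simulation
NULL

#' Derive deterministic sub-seeds from a master seed
#'
#' Draws `n` integer seeds (each below `.Machine$integer.max`) from the
#' stream identified by `seed`, so independent simulation stages can be
#' seeded reproducibly from a single master seed.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Plan the physical eyes of a cohort
#'
#' Expands a preset table into one row per physical eye, pairing the
#' HVO_HVO and N2_HVO hemifield groups onto shared eyes when both are
#' present.
#'
#' @param presets a preset table ([group_presets()] or a subset).
#' @param n_eyes_per_group eyes per study group (>= 1).
#' @param seed master seed; fixes the affected-hemifield draws and per-eye
#'   sub-seeds.
#' @return data.frame with `eye_id`, `participant_id`, `demo_group`
#'   (demographics source), `superior_group`, `inferior_group`, `eye_seed`.
#' @export
make_eye_plan <- function(presets, n_eyes_per_group, seed) {
  if (n_eyes_per_group < 1) stop("n_eyes_per_group must be >= 1")
  validate_presets(presets)
  groups <- presets$group_id
  paired <- all(c("HVO_HVO", "N2_HVO") %in% groups)
  unit_groups <- if (paired) setdiff(groups, "N2_HVO") else groups

  n_units <- length(unit_groups) * n_eyes_per_group
  seeds <- derive_seeds(seed, n_units + 1)
  set.seed(seeds[n_units + 1])
  affected_sup <- stats::runif(n_units) < 0.5

  rows <- list()
  i <- 0L
  for (g in unit_groups) {
    for (k in seq_len(n_eyes_per_group)) {
      i <- i + 1L
      if (paired && g == "HVO_HVO") {
        sup <- if (affected_sup[i]) "HVO_HVO" else "N2_HVO"
        inf <- if (affected_sup[i]) "N2_HVO" else "HVO_HVO"
      } else {
        sup <- inf <- g
      }
      rows[[i]] <- data.frame(
        eye_id = sprintf("eye%03d", i),
        participant_id = sprintf("p%03d", i),
        demo_group = g, superior_group = sup, inferior_group = inf,
        eye_seed = seeds[i],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Simulate one synthetic eye
#'
#' Builds the vessel tree, draws the per-eye amplitude offset and
#' demographics, lays the ground-truth field, and renders one recording per
#' ODF level. Fully reproducible from `seed`.
#'
#' @param superior_group,inferior_group study-group ids applied to each
#'   hemifield (identical for non-HVO eyes).
#' @param config a [sim_config()].
#' @param seed integer seed for this eye.
#' @param eye_id,participant_id identifiers.
#' @param demo_group group id whose demographics (age, POAG) and rendering
#'   parameters are used; defaults to `superior_group`.
#' @param presets preset table to look groups up in.
#' @return list of class `ppg_eye`: `eye` (one-row data.frame of
#'   identifiers, groups, covariates, `eye_offset`), `seg`, `truth`,
#'   `recordings` (per ODF level: `odf` record, `video`, `timing`).
#' @export
simulate_eye <- function(superior_group, inferior_group = superior_group,
                         config = sim_config(), seed = config$seed,
                         eye_id = "eye001", participant_id = "p001",
                         demo_group = superior_group,
                         presets = group_presets()) {
  for (g in c(superior_group, inferior_group, demo_group)) {
    if (!g %in% presets$group_id) stop("unknown group_id: ", g)
  }
  prow <- function(g) presets[presets$group_id == g, , drop = FALSE]
  demo <- prow(demo_group)

  seeds <- derive_seeds(seed, 2 + length(config$odf_levels))
  tree <- make_vessel_tree(config, seed = seeds[1])

  set.seed(seeds[2])
  eye_offset <- stats::rnorm(1, 0, demo$between_eye_sd)
  age <- stats::rnorm(1, demo$age_mean, demo$age_sd)
  sex <- sample(c("male", "female"), 1)
  poag <- stats::runif(1) < demo$poag_prevalence
  laterality <- sample(c("right", "left"), 1)

  truth <- amplitude_field(
    list(superior = prow(superior_group), inferior = prow(inferior_group)),
    tree, eye_offset = eye_offset
  )

  recordings <- lapply(seq_along(config$odf_levels), function(i) {
    r <- render_frames(truth, tree, config, demo, seed = seeds[2 + i])
    list(odf = odf_record(config$odf_levels[i], config$baseline_iop),
         video = r$video, timing = r$timing)
  })

  structure(
    list(
      eye = data.frame(
        eye_id = eye_id, participant_id = participant_id,
        superior_group = superior_group, inferior_group = inferior_group,
        demo_group = demo_group,
        age = age, sex = sex, poag = poag, laterality = laterality,
        eye_offset = eye_offset, stringsAsFactors = FALSE
      ),
      seg = tree, truth = truth, recordings = recordings
    ),
    class = "ppg_eye"
  )
}

#' Generate a full synthetic cohort
#'
#' Materialises every eye of the plan (frames included). For large cohorts
#' prefer [run_cohort()], which analyses each eye as it is generated and
#' never holds more than one eye's frames in memory.
#'
#' @inheritParams make_eye_plan
#' @param config a [sim_config()].
#' @param seed master seed.
#' @return list of class `ppg_cohort`: `eyes` (list of `ppg_eye`), `plan`,
#'   `config`, `presets`.
#' @export
generate_cohort <- function(presets = group_presets(), n_eyes_per_group = 1,
                            config = sim_config(), seed = config$seed) {
  plan <- make_eye_plan(presets, n_eyes_per_group, seed)
  eyes <- lapply(seq_len(nrow(plan)), function(i) {
    p <- plan[i, ]
    simulate_eye(p$superior_group, p$inferior_group, config,
                 seed = p$eye_seed, eye_id = p$eye_id,
                 participant_id = p$participant_id,
                 demo_group = p$demo_group, presets = presets)
  })
  structure(list(eyes = eyes, plan = plan, config = config,
                 presets = presets),
            class = "ppg_cohort")
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cat("ppg_cohort:", length(x$eyes), "eyes\n")
  print(table(x$plan$demo_group))
  invisible(x)
}

#' Simulate vessel observations directly (statistical layer)
#'
#' Draws per-vessel, per-ODF observation tables straight from the group
#' presets, bypassing video rendering and harmonic fitting: each
#' observation's mean log amplitude is the preset mean plus the eye's random
#' offset plus independent measurement noise, the maximum sits a fixed step
#' above the mean, and the slope scatters around the preset slope. This
#' layer feeds the mixed-model calibration and type-I-error simulations,
#' where hundreds of cohort replicates are needed and the imaging stages --
#' validated separately -- would only add cost.
#'
#' @inheritParams make_eye_plan
#' @param odf_levels force levels per eye (Meditron units).
#' @param baseline_iop baseline IOP, mm Hg.
#' @param n_vessels_per_type vessels of each type per hemifield.
#' @param obs_sd measurement noise SD of an observation's mean log amplitude
#'   (log u).
#' @param slope_sd per-observation scatter of the attenuation slope
#'   (log u/mm).
#' @param max_step offset of the maximum above the mean log amplitude (log u).
#' @return a cohort observation data.frame (one row per vessel x ODF) with
#'   covariates, as produced by the full pipeline.
#' @export
simulate_observations <- function(presets = group_presets(),
                                  n_eyes_per_group = 10,
                                  odf_levels = c(0, 20, 40),
                                  baseline_iop = 16,
                                  n_vessels_per_type = 1,
                                  obs_sd = 0.08, slope_sd = 0.05,
                                  max_step = 0.3,
                                  seed = 1L) {
  plan <- make_eye_plan(presets, n_eyes_per_group, seed)
  seeds <- derive_seeds(seed + 1L, nrow(plan))
  prow <- function(g) presets[presets$group_id == g, , drop = FALSE]
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    demo <- prow(p$demo_group)
    set.seed(seeds[i])
    eye_offset <- stats::rnorm(1, 0, demo$between_eye_sd)
    age <- stats::rnorm(1, demo$age_mean, demo$age_sd)
    sex <- sample(c("male", "female"), 1)
    poag <- stats::runif(1) < demo$poag_prevalence
    laterality <- sample(c("right", "left"), 1)
    rows <- list()
    vid <- 0L
    for (hemi in c("superior", "inferior")) {
      g <- if (hemi == "superior") p$superior_group else p$inferior_group
      pr <- prow(g)
      for (lab in c("vein", "artery")) {
        mu <- if (lab == "vein") pr$venous_mean_logamp else pr$arterial_mean_logamp
        sl <- if (lab == "vein") pr$venous_slope else pr$arterial_slope
        for (v in seq_len(n_vessels_per_type)) {
          vid <- vid + 1L
          for (odf in odf_levels) {
            m <- mu + eye_offset + stats::rnorm(1, 0, obs_sd)
            rows[[length(rows) + 1]] <- data.frame(
              eye_id = p$eye_id, participant_id = p$participant_id,
              vessel_id = vid, vessel_label = lab, hemifield = hemi,
              group_id = g, odf = odf,
              induced_iop = induced_iop(odf, baseline_iop),
              mean_logamp = m,
              max_logamp = m + max_step + abs(stats::rnorm(1, 0, obs_sd)),
              slope = sl + stats::rnorm(1, 0, slope_sd),
              slope_se = slope_sd, n_loci = NA_integer_,
              age = age, sex = sex, poag = poag, laterality = laterality,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a generated cohort to disk
#'
#' Lays out one directory per eye holding the per-ODF frame stacks
#' (multi-page 16-bit TIFF + JSON timing sidecar), the segmentation
#' (indexed PNG + JSON sidecar), beep-timing and ODF CSVs, and the truth
#' tables, under a cohort manifest (`manifest.yaml`).
#'
#' @param cohort a `ppg_cohort` from [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (eye in cohort$eyes) {
    ed <- file.path(dir, eye$eye$eye_id)
    dir.create(ed, showWarnings = FALSE)
    write_segmentation(eye$seg, file.path(ed, "segmentation.png"))
    write_truth(eye$truth, ed)
    odf_tab <- do.call(rbind, lapply(eye$recordings, function(r) {
      data.frame(odf = r$odf$odf, baseline_iop = r$odf$baseline_iop,
                 induced_iop = r$odf$induced_iop)
    }))
    utils::write.csv(odf_tab, file.path(ed, "odf.csv"), row.names = FALSE)
    for (j in seq_along(eye$recordings)) {
      r <- eye$recordings[[j]]
      stem <- sprintf("recording_odf%03d", r$odf$odf)
      write_stack(r$video, file.path(ed, paste0(stem, ".tif")))
      write_timing(r$timing, file.path(ed, paste0(stem, "_beeps.csv")))
    }
    utils::write.csv(eye$eye, file.path(ed, "eye.csv"), row.names = FALSE)
  }
  manifest <- list(
    n_eyes = length(cohort$eyes),
    eyes = cohort$plan$eye_id,
    groups = unname(cohort$plan$demo_group),
    image_size = cohort$config$image_size,
    microns_per_pixel = cohort$config$microns_per_pixel,
    frame_rate = cohort$config$frame_rate,
    odf_levels = cohort$config$odf_levels
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
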