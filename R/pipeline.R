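#' Analyse one eye end to end
#'
#' Runs the full locus pipeline on every recording of a synthetic or loaded
#' eye: trim to `n_cycles` complete cardiac cycles, assemble 5x5-pixel locus
#' series over arteries and veins, fit the harmonic regression at each valid
#' locus, map fits into disc-centred polar coordinates, restrict to the
#' 0.25--1 mm annulus, and reduce to per-vessel observations at each force
#' level. Eye covariates are joined onto the observation rows.
#'
#' @param eye a `ppg_eye` from [simulate_eye()], or any list with `eye`
#'   (covariate row), `seg`, and `recordings` (each holding `odf`, `video`,
#'   `timing`).
#' @param n_cycles cycles to analyse (default 3).
#' @param align logical; run [align_frames()] first (default `FALSE`:
#'   synthetic eyes are born aligned).
#' @param cluster locus size in pixels.
#' @param keep_maps logical; also return the annulus-filtered amplitude map
#'   of each recording (memory permitting).
#' @param ... forwarded to [fit_loci()] (e.g. `amplitude_method`).
#' @return list with `observations` (data.frame, one row per vessel x ODF,
#'   with covariates) and, when `keep_maps`, `maps`.
#' @export
analyze_eye <- function(eye, n_cycles = 3, align = FALSE, cluster = 5,
                        keep_maps = FALSE, ...) {
  geometry <- disc_geometry(eye$seg)
  hemi_groups <- c(superior = eye$eye$superior_group,
                   inferior = eye$eye$inferior_group)
  obs <- list(); maps <- list()
  for (i in seq_along(eye$recordings)) {
    rec <- eye$recordings[[i]]
    video <- rec$video
    if (align) video <- align_frames(video)$video
    video <- trim_cycles(video, rec$timing, n = n_cycles)
    period <- estimate_period(rec$timing)
    ls <- assemble_loci(video, eye$seg, cluster = cluster)
    fits <- fit_loci(ls, period = period, ...)
    map <- annulus_filter(amplitude_map(fits, geometry))
    o <- summarize_vessels(map, rec$odf,
                           eye_id = eye$eye$eye_id,
                           participant_id = eye$eye$participant_id,
                           group_by_hemifield = hemi_groups)
    if (!is.null(o)) {
      o$age <- eye$eye$age
      o$sex <- eye$eye$sex
      o$poag <- eye$eye$poag
      o$laterality <- eye$eye$laterality
      obs[[i]] <- o
    }
    if (keep_maps) maps[[i]] <- map
  }
  out <- list(observations = do.call(rbind, obs))
  if (keep_maps) out$maps <- maps
  out
}

#' Simulate and analyse a cohort, eye by eye
#'
#' Streams the full pipeline over a cohort plan: each eye is generated,
#' analysed, and its frames discarded before the next is rendered, so memory
#' stays flat regardless of cohort size. Returns the stacked observation
#' table plus the per-vessel ground truth for recovery checks.
#'
#' @inheritParams generate_cohort
#' @param ... forwarded to [analyze_eye()].
#' @return list with `observations` (cohort observation table),
#'   `truth_vessels` (per-vessel truth with `eye_id`), and `plan`.
#' @export
run_cohort <- function(presets = group_presets(), n_eyes_per_group = 1,
                       config = sim_config(), seed = config$seed, ...) {
  plan <- make_eye_plan(presets, n_eyes_per_group, seed)
  obs <- list(); truths <- list()
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    eye <- simulate_eye(p$superior_group, p$inferior_group, config,
                        seed = p$eye_seed, eye_id = p$eye_id,
                        participant_id = p$participant_id,
                        demo_group = p$demo_group, presets = presets)
    res <- analyze_eye(eye, n_cycles = config$n_cycles, ...)
    obs[[i]] <- res$observations
    tv <- eye$truth$vessels
    tv$eye_id <- p$eye_id
    truths[[i]] <- tv
    rm(eye)
  }
  list(
    observations = do.call(rbind, obs),
    truth_vessels = do.call(rbind, truths),
    plan = plan
  )
}

#' Per-eye and cohort-level amplitude summaries
#'
#' Collapses an observation table the way the cohort results are reported:
#' per eye (within study group and vessel type) the mean over vessels and
#' force levels of the observation's mean log amplitude, maximum log
#' amplitude and attenuation slope; then per group the across-eye mean, SD,
#' and simulation standard error (SD / sqrt(n eyes)).
#'
#' @param observations a cohort observation table.
#' @return data.frame, one row per group x vessel type: `group_id`,
#'   `vessel_label`, `n_eyes`, `mean_logamp`, `sd_logamp`, `se_logamp`,
#'   `max_logamp`, `slope`, `sd_slope`, `se_slope`.
#' @export
cohort_summary <- function(observations) {
  key <- interaction(observations$group_id, observations$vessel_label,
                     observations$eye_id, drop = TRUE)
  eye_tab <- do.call(rbind, lapply(split(observations, key), function(d) {
    data.frame(
      group_id = d$group_id[1], vessel_label = d$vessel_label[1],
      eye_id = d$eye_id[1],
      mean_logamp = mean(d$mean_logamp),
      max_logamp = mean(d$max_logamp),
      slope = mean(d$slope, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  key2 <- interaction(eye_tab$group_id, eye_tab$vessel_label, drop = TRUE)
  out <- do.call(rbind, lapply(split(eye_tab, key2), function(d) {
    n <- nrow(d)
    data.frame(
      group_id = d$group_id[1], vessel_label = d$vessel_label[1],
      n_eyes = n,
      mean_logamp = mean(d$mean_logamp),
      sd_logamp = stats::sd(d$mean_logamp),
      se_logamp = stats::sd(d$mean_logamp) / sqrt(n),
      max_logamp = mean(d$max_logamp),
      slope = mean(d$slope, na.rm = TRUE),
      sd_slope = stats::sd(d$slope),
      se_slope = stats::sd(d$slope) / sqrt(n),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
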