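#' Induced intraocular pressure under ophthalmodynamometric force
#'
#' Converts an applied ophthalmodynamometric force (ODF, Meditron units)
#' into the induced intraocular pressure using the calibration
#' `induced IOP = 0.89 x ODF + baseline IOP`.
#'
#' @param odf ophthalmodynamometric force, Meditron units (mu), >= 0.
#' @param baseline baseline intraocular pressure, mm Hg.
#' @return induced IOP in mm Hg.
#' @export
#' @examples
#' induced_iop(50, 10)  # 54.5 mm Hg
induced_iop <- function(odf, baseline) {
  if (any(odf < 0)) stop("ODF must be >= 0")
  0.89 * odf + baseline
}

#' An ophthalmodynamometric force record
#'
#' Bundles one force application: the ODF in Meditron units (1 mu = 3.33 g
#' of force), the baseline IOP and the induced IOP.
#'
#' @param odf force in Meditron units, >= 0.
#' @param baseline_iop baseline intraocular pressure, mm Hg.
#' @return list of class `odf_record` with `odf`, `baseline_iop`,
#'   `induced_iop`, `grams_force`.
#' @export
odf_record <- function(odf, baseline_iop) {
  structure(
    list(odf = odf, baseline_iop = baseline_iop,
         induced_iop = induced_iop(odf, baseline_iop),
         grams_force = 3.33 * odf),
    class = "odf_record"
  )
}

#' Attenuation slope of log amplitude along a vessel
#'
#' Ordinary least-squares slope of locus log amplitude on radial distance
#' from the disc centre (log u/mm). Negative slopes indicate pulse-wave
#' attenuation along the vessel. The fit requires at least `min_loci` loci
#' spanning at least `min_span` mm of radial distance; degenerate inputs
#' yield missing values rather than an error.
#'
#' @param d_mm radial distances (mm).
#' @param log_amplitude locus log amplitudes (log u).
#' @param min_loci minimum number of loci (default 5).
#' @param min_span minimum radial span in mm (default 0.2).
#' @return list with `slope`, `se`, `intercept` (all `NA` when degenerate).
#' @export
#' @examples
#' amplitude_slope(c(0.25, 0.5, 0.75, 1), c(2, 1.8, 1.6, 1.4),
#'                 min_loci = 4)$slope  # -0.8
amplitude_slope <- function(d_mm, log_amplitude, min_loci = 5,
                            min_span = 0.2) {
  if (length(d_mm) < min_loci || diff(range(d_mm)) < min_span) {
    return(list(slope = NA_real_, se = NA_real_, intercept = NA_real_))
  }
  fit <- stats::lm(log_amplitude ~ d_mm)
  # noiseless inputs fit perfectly; the summary warning is expected there
  cf <- suppressWarnings(summary(fit)$coefficients)
  list(slope = cf["d_mm", "Estimate"], se = cf["d_mm", "Std. Error"],
       intercept = cf["(Intercept)", "Estimate"])
}

#' Summarise one vessel at one force level
#'
#' Reduces a vessel's annulus loci to the per-vessel, per-ODF observation:
#' mean and maximum log amplitude and the attenuation slope, together with
#' the induced IOP. Returns `NULL` (with a message) when the vessel has no
#' retained loci.
#'
#' @param map an annulus-filtered `amplitude_map`.
#' @param vessel_id vessel to summarise.
#' @param odf an `odf_record`.
#' @param eye_id,participant_id,group_id,hemifield identifiers carried into
#'   the observation (defaults taken from the map rows where possible).
#' @param min_loci,min_span slope requirements, see [amplitude_slope()].
#' @return one-row data.frame (a vessel observation) or `NULL`.
#' @export
summarize_vessel <- function(map, vessel_id, odf,
                             eye_id = NA, participant_id = NA,
                             group_id = NA, hemifield = NULL,
                             min_loci = 5, min_span = 0.2) {
  rows <- map[map$vessel_id == vessel_id, , drop = FALSE]
  if (!nrow(rows)) {
    message("vessel ", vessel_id, ": no retained annulus loci; observation skipped")
    return(NULL)
  }
  sl <- amplitude_slope(rows$d_mm, rows$log_amplitude,
                        min_loci = min_loci, min_span = min_span)
  data.frame(
    eye_id = eye_id, participant_id = participant_id,
    vessel_id = vessel_id,
    vessel_label = rows$label[1],
    hemifield = if (is.null(hemifield)) rows$hemifield[1] else hemifield,
    group_id = group_id,
    odf = odf$odf, induced_iop = odf$induced_iop,
    mean_logamp = mean(rows$log_amplitude),
    max_logamp = max(rows$log_amplitude),
    slope = sl$slope, slope_se = sl$se,
    n_loci = nrow(rows),
    stringsAsFactors = FALSE
  )
}

#' Summarise every artery and vein in an amplitude map
#'
#' @param map an annulus-filtered `amplitude_map`.
#' @param odf an `odf_record`.
#' @param eye_id,participant_id identifiers for the observations.
#' @param group_by_hemifield optional named character vector
#'   `c(superior = , inferior = )` assigning a study group per hemifield
#'   (hemifield-split HVO eyes); a plain single string assigns one group to
#'   the whole eye.
#' @param ... forwarded to [summarize_vessel()].
#' @return data.frame of vessel observations, one row per vessel.
#' @export
summarize_vessels <- function(map, odf, eye_id = NA, participant_id = NA,
                              group_by_hemifield = NA, ...) {
  ids <- unique(map$vessel_id)
  out <- lapply(ids, function(v) {
    hemi <- map$hemifield[map$vessel_id == v][1]
    grp <- if (length(group_by_hemifield) == 1 && is.null(names(group_by_hemifield))) {
      group_by_hemifield
    } else {
      unname(group_by_hemifield[hemi])
    }
    summarize_vessel(map, v, odf, eye_id = eye_id,
                     participant_id = participant_id,
                     group_id = grp, hemifield = hemi, ...)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a vessel-observation table
#'
#' The observations CSV (one row per vessel per ODF level) is the interface
#' between the imaging pipeline and the cohort statistics.
#'
#' @param observations data.frame of vessel observations.
#' @param path CSV path.
#' @return `path` / the observation data.frame.
#' @export
write_observations <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
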