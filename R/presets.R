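#' Study-group presets for the synthetic cohort generator
#'
#' Returns the table of per-group generator parameters. Each row defines the
#' cohort-level truth for one of the six study groups used in central forms of
#' retinal venous occlusion research:
#' \describe{
#'   \item{N1_N1}{normal eyes of normal participants}
#'   \item{N1_CRVO}{unaffected fellow eyes of CRVO participants}
#'   \item{N1_HVO}{unaffected fellow eyes of HVO participants}
#'   \item{N2_HVO}{unaffected hemivessels of HVO eyes}
#'   \item{HVO_HVO}{affected hemivessels of HVO eyes}
#'   \item{CRVO_CRVO}{eyes with central retinal vein occlusion}
#' }
#'
#' Centre values (`venous_mean_logamp`, `venous_slope`, `arterial_mean_logamp`
#' and, for the normal and CRVO groups, `arterial_slope`) are the published
#' cohort summaries for these groups, so that parameter-recovery tests target
#' reported numbers. Arterial slopes for the intermediate groups are not
#' separately reported and are set to follow the same occlusion-related
#' flattening trend as the veins. `between_eye_sd` defaults to the reported
#' dispersion of the venous mean, interpreted as a between-eye standard
#' deviation; a single per-eye offset shifts the venous and arterial fields
#' jointly.
#'
#' Age distributions (`age_mean`, `age_sd`) and POAG prevalence follow the
#' study's per-group demographics (SDs back-computed from 95% confidence
#' intervals of the mean).
#'
#' @param group_id optional character vector; subset and order the table by
#'   these group ids.
#' @return a data.frame of class `ppg_presets`, one row per group, columns:
#'   `group_id`, `venous_mean_logamp` (log u), `venous_slope` (log u/mm),
#'   `arterial_mean_logamp` (log u), `arterial_slope` (log u/mm),
#'   `between_eye_sd` (log u), `harmonic2_fraction`, `ar_coefficient`,
#'   `noise_sd` (intensity units), `drift_magnitude` (intensity units),
#'   `age_mean` (years), `age_sd` (years), `poag_prevalence`.
#' @export
#' @examples
#' group_presets()
#' group_presets("CRVO_CRVO")
group_presets <- function(group_id = NULL) {
  tab <- data.frame(
    group_id = c("N1_N1", "N1_CRVO", "N1_HVO", "N2_HVO", "HVO_HVO", "CRVO_CRVO"),
    venous_mean_logamp   = c(2.08, 1.76, 1.33, 1.30, 1.23, 0.99),
    venous_slope         = c(-0.80, -0.54, -0.63, -0.005, 0.000, 0.35),
    arterial_mean_logamp = c(1.56, 1.23, 1.09, 1.23, 1.15, 0.91),
    arterial_slope       = c(-0.44, -0.30, -0.35, -0.05, 0.00, 0.26),
    between_eye_sd       = c(0.48, 0.34, 0.37, 0.59, 0.46, 0.45),
    harmonic2_fraction   = 0.2,
    ar_coefficient       = 0.5,
    noise_sd             = 1.0,
    drift_magnitude      = 2.0,
    age_mean             = c(59.52, 57.25, 73.20, 74.38, 74.38, 70.24),
    age_sd               = c(19.46, 16.80, 5.93, 5.88, 5.88, 13.54),
    poag_prevalence      = c(0, 1, 1, 7 / 8, 7 / 8, 8 / 21),
    stringsAsFactors = FALSE
  )
  if (!is.null(group_id)) {
    missing <- setdiff(group_id, tab$group_id)
    if (length(missing)) {
      stop("unknown group_id: ", paste(missing, collapse = ", "))
    }
    tab <- tab[match(group_id, tab$group_id), , drop = FALSE]
    rownames(tab) <- NULL
  }
  validate_presets(tab)
  class(tab) <- c("ppg_presets", "data.frame")
  tab
}

#' Validate a preset table
#'
#' Checks the invariants every generator preset must satisfy: AR coefficient
#' strictly inside (-1, 1), non-negative noise, second-harmonic energy
#' fraction in \[0, 1\], unique group ids.
#'
#' @param presets a data.frame with the columns of [group_presets()].
#' @return the table, invisibly, on success; errors otherwise.
#' @export
validate_presets <- function(presets) {
  stopifnot(is.data.frame(presets))
  needed <- c(
    "group_id", "venous_mean_logamp", "venous_slope", "arterial_mean_logamp",
    "arterial_slope", "between_eye_sd", "harmonic2_fraction",
    "ar_coefficient", "noise_sd", "drift_magnitude"
  )
  miss <- setdiff(needed, names(presets))
  if (length(miss)) stop("preset table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(presets$group_id)) stop("group_id must be unique within a preset table")
  if (any(abs(presets$ar_coefficient) >= 1)) stop("ar_coefficient must satisfy |phi| < 1")
  if (any(presets$noise_sd < 0)) stop("noise_sd must be >= 0")
  if (any(presets$harmonic2_fraction < 0 | presets$harmonic2_fraction > 1)) {
    stop("harmonic2_fraction must lie in [0, 1]")
  }
  if (any(presets$between_eye_sd < 0)) stop("between_eye_sd must be >= 0")
  invisible(presets)
}
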