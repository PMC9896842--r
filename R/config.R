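#' Simulation configuration
#'
#' Assembles and validates the acquisition geometry and timing used by the
#' synthetic fundus-video generator. Defaults encode the study conditions the
#' pipeline is designed for: three cardiac cycles of green-channel video, a
#' 30 micron locus equal to a 5x5-pixel cluster (6 micron pixels), and an
#' ophthalmodynamometric force (ODF) sweep giving induced intraocular
#' pressures spanning the reported range.
#'
#' @param frame_rate frames per second (default 25; capture rate is a declared
#'   default, not a measured quantity).
#' @param cardiac_period cardiac cycle length in seconds (default 1.0).
#' @param n_cycles number of cardiac cycles recorded (default 3).
#' @param image_size frame side length in pixels (square frames).
#' @param microns_per_pixel spatial scale, micrometres per pixel (default 6,
#'   from 30 micron = 5 px).
#' @param disc_center optic-disc centre as (row, col), 1-based; default the
#'   frame centre.
#' @param disc_radius optic disc radius in mm.
#' @param cup_radius optic cup radius in mm.
#' @param n_vessels_per_type number of vessels of each type (artery, vein)
#'   per hemifield.
#' @param vessel_inner_mm radial distance (mm) at which vessel paths emerge
#'   from the cup region.
#' @param vessel_outer_mm radial distance (mm) to which vessel paths extend;
#'   must exceed 1 mm so the full analysis annulus is covered.
#' @param vein_width_um,artery_width_um vessel widths in micrometres.
#' @param odf_levels ophthalmodynamometric force levels (Meditron units, mu)
#'   applied per eye.
#' @param baseline_iop baseline intraocular pressure, mm Hg.
#' @param background_level,disc_level,cup_level,vessel_base_level baseline
#'   intensities (arbitrary units) of the rendered tissue classes.
#' @param seed default integer seed for generator calls that do not pass one.
#' @return a list of class `ppg_config`.
#' @export
#' @examples
#' cfg <- sim_config()
#' cfg$frame_rate * cfg$cardiac_period  # samples per cardiac cycle
sim_config <- function(frame_rate = 25,
                       cardiac_period = 1.0,
                       n_cycles = 3,
                       image_size = 400,
                       microns_per_pixel = 6,
                       disc_center = NULL,
                       disc_radius = 0.75,
                       cup_radius = 0.25,
                       n_vessels_per_type = 1,
                       vessel_inner_mm = 0.12,
                       vessel_outer_mm = 1.1,
                       vein_width_um = 90,
                       artery_width_um = 72,
                       odf_levels = c(0, 20, 40),
                       baseline_iop = 16,
                       background_level = 180,
                       disc_level = 220,
                       cup_level = 240,
                       vessel_base_level = 120,
                       seed = 1L) {
  if (is.null(disc_center)) {
    disc_center <- c(ceiling(image_size / 2), ceiling(image_size / 2))
  }
  cfg <- list(
    frame_rate = frame_rate, cardiac_period = cardiac_period,
    n_cycles = n_cycles, image_size = as.integer(image_size),
    microns_per_pixel = microns_per_pixel,
    disc_center = as.numeric(disc_center),
    disc_radius = disc_radius, cup_radius = cup_radius,
    n_vessels_per_type = as.integer(n_vessels_per_type),
    vessel_inner_mm = vessel_inner_mm, vessel_outer_mm = vessel_outer_mm,
    vein_width_um = vein_width_um, artery_width_um = artery_width_um,
    odf_levels = odf_levels, baseline_iop = baseline_iop,
    background_level = background_level, disc_level = disc_level,
    cup_level = cup_level, vessel_base_level = vessel_base_level,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "ppg_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_cycles < 1) stop("n_cycles must be >= 1")
  if (cfg$frame_rate * cfg$cardiac_period < 8) {
    stop(
      "frame_rate x cardiac_period must be >= 8 samples per cycle ",
      "(two harmonics cannot be resolved otherwise)"
    )
  }
  if (cfg$microns_per_pixel <= 0) stop("microns_per_pixel must be > 0")
  if (cfg$vessel_outer_mm <= 1) stop("vessel_outer_mm must exceed 1 mm")
  if (any(cfg$odf_levels < 0)) stop("odf_levels must be >= 0")
  if (length(cfg$disc_center) != 2) stop("disc_center must be (row, col)")
  invisible(cfg)
}

#' Number of frames per recording implied by a configuration
#' @param config a `ppg_config`.
#' @return integer frame count.
#' @keywords internal
n_frames <- function(config) {
  as.integer(round(config$n_cycles * config$cardiac_period * config$frame_rate))
}
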