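#' Disc-centred polar coordinates
#'
#' Converts pixel coordinates to polar coordinates about the optic-disc
#' centre. Distances are in millimetres (`Euclidean pixel distance x
#' microns_per_pixel / 1000`); angles are measured from the horizontal image
#' axis, counter-clockwise with "up" (smaller row indices, anatomically
#' superior) positive, in degrees in (-180, 180].
#'
#' @param pixels numeric matrix or data.frame with two columns (row, col),
#'   1-based, or a length-2 vector for a single pixel.
#' @param geometry a `ppg_geometry` from [disc_geometry()], or any list with
#'   `disc_center` and `microns_per_pixel`.
#' @return data.frame with columns `d_mm` and `angle_deg`.
#' @export
#' @examples
#' g <- structure(list(disc_center = c(200, 200), microns_per_pixel = 6),
#'                class = "ppg_geometry")
#' to_polar(c(150, 200), g)  # 50 px above centre: d = 0.3 mm, angle = 90
to_polar <- function(pixels, geometry) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2)
  pixels <- as.matrix(pixels)
  dx <- (pixels[, 2] - geometry$disc_center[2])
  dy <- (geometry$disc_center[1] - pixels[, 1])
  d_mm <- sqrt(dx^2 + dy^2) * geometry$microns_per_pixel / 1000
  angle <- atan2(dy, dx) * 180 / pi
  angle[angle <= -180] <- 180
  data.frame(d_mm = d_mm, angle_deg = angle)
}

#' Build an amplitude map from per-locus harmonic fits
#'
#' Attaches disc-centred polar coordinates and hemifield tags to a table of
#' per-locus fits, producing the locus-level amplitude map used for annulus
#' filtering, heat mapping and vessel summaries.
#'
#' @param fits per-locus fit table from [fit_loci()] (columns `center_row`,
#'   `center_col`, `label`, `vessel_id`, `amplitude`, `log_amplitude`, ...).
#' @param geometry a `ppg_geometry`.
#' @return the fit table with `d_mm`, `angle_deg` and `hemifield` columns,
#'   class `amplitude_map`.
#' @export
amplitude_map <- function(fits, geometry) {
  pol <- to_polar(cbind(fits$center_row, fits$center_col), geometry)
  fits$d_mm <- pol$d_mm
  fits$angle_deg <- pol$angle_deg
  fits <- split_hemifield(fits)
  class(fits) <- c("amplitude_map", "data.frame")
  fits
}

#' Restrict an amplitude map to the peripapillary annulus
#'
#' Retains loci with radial distance in the closed interval
#' `[inner, outer]` mm from the disc centre. The default 0.25--1 mm window
#' excludes the small rising phase of pulsation close to the disc centre and
#' keeps the attenuation segment of the pulse distribution.
#'
#' @param map an `amplitude_map`.
#' @param inner,outer annulus bounds in mm (closed interval).
#' @return the filtered map; the number of removed loci is recorded in
#'   attribute `n_removed`. Idempotent.
#' @export
annulus_filter <- function(map, inner = 0.25, outer = 1.0) {
  if (inner >= outer) stop("annulus inner bound must be smaller than outer bound")
  keep <- map$d_mm >= inner & map$d_mm <= outer
  out <- map[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- c("amplitude_map", "data.frame")
  out
}

#' Tag loci with their retinal hemifield
#'
#' Loci with polar angle in (0, 180) degrees -- image rows above the disc
#' centre -- are tagged superior, loci with negative angle inferior. Loci
#' exactly on the horizontal axis (angle 0 or 180) inherit the hemifield of
#' their vessel's mean angle, so a vessel straddling the axis is never split
#' by the tie.
#'
#' @param map a data.frame with `angle_deg` and `vessel_id` columns.
#' @return the map with a `hemifield` column.
#' @export
split_hemifield <- function(map) {
  ang <- map$angle_deg
  hemi <- ifelse(ang > 0 & ang < 180, "superior", "inferior")
  on_axis <- ang == 0 | ang == 180
  if (any(on_axis)) {
    for (v in unique(map$vessel_id[on_axis])) {
      sel <- map$vessel_id == v
      mean_ang <- mean(ang[sel])
      hemi[sel & on_axis] <-
        if (mean_ang > 0 && mean_ang < 180) "superior" else "inferior"
    }
  }
  map$hemifield <- hemi
  map
}
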