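#' Ground-truth log-amplitude field for a synthetic eye
#'
#' Lays a log-linear pulse-amplitude field over every vessel pixel: at radial
#' distance `d` mm from the disc centre the true log amplitude is
#' `intercept + slope * d`, with the vessel-type slope taken from the group
#' preset of the pixel's hemifield. The intercept of each vessel is
#' calibrated so that the mean over its valid 0.25--1 mm annulus *loci*
#' (5x5-pixel clusters, the pipeline's observable -- each locus's effective
#' log amplitude is the log of the mean amplitude over its labelled pixels)
#' equals the preset's mean log amplitude plus the per-eye offset. With a
#' zero offset the annulus locus mean therefore reproduces the preset mean
#' exactly.
#'
#' `other_vessel` pixels receive a nominal constant amplitude so every
#' vessel pixel carries truth; they are never analysed.
#'
#' @param preset single-row preset (see [group_presets()]) applied to both
#'   hemifields, or a named list `list(superior = , inferior = )` of
#'   single-row presets for hemifield-split (HVO) eyes.
#' @param tree a `ppg_segmentation` from [make_vessel_tree()].
#' @param geometry a `ppg_geometry`; defaults to the tree's own.
#' @param eye_offset per-eye random intercept shift in log u (draw it with
#'   sd `between_eye_sd`; default 0).
#' @param cluster locus size in pixels (must match the analysis tiling).
#' @return object of class `ppg_truth`: list with
#'   \describe{
#'     \item{pixels}{data.frame `row`, `col`, `vessel_id`, `label`, `d_mm`,
#'       `log_amplitude`, `amplitude` for every vessel pixel;}
#'     \item{loci}{data.frame of effective truth per valid annulus locus
#'       (`locus_id`, `vessel_id`, `label`, `hemifield`, `d_mm`,
#'       `log_amplitude`);}
#'     \item{vessels}{data.frame per analysed vessel: `vessel_id`, `label`,
#'       `hemifield`, `group_id`, `mean_logamp` (the calibrated target),
#'       `max_logamp`, `slope` (OLS of locus truth on distance),
#'       `preset_slope`, `intercept`, `n_loci`;}
#'     \item{eye_offset}{the offset used.}
#'   }
#' @export
amplitude_field <- function(preset, tree, geometry = disc_geometry(tree),
                            eye_offset = 0, cluster = 5) {
  presets <- if (is.data.frame(preset)) {
    list(superior = preset, inferior = preset)
  } else {
    stopifnot(all(c("superior", "inferior") %in% names(preset)))
    preset
  }
  for (p in presets) stopifnot(is.data.frame(p), nrow(p) == 1)
  if (is.null(tree$vessel_id)) tree <- label_vessels(tree)

  grid <- locus_grid(tree, labels = c("artery", "vein"), cluster = cluster)
  gl <- grid$loci
  pol_loci <- to_polar(cbind(gl$center_row, gl$center_col), geometry)
  gl$d_mm <- pol_loci$d_mm
  annulus_locus <- gl$valid & gl$d_mm >= 0.25 & gl$d_mm <= 1.0

  nr <- nrow(tree$labels)
  pix_rows <- list(); vrows <- list(); lrows <- list()
  for (i in seq_len(nrow(tree$vessels))) {
    v <- tree$vessels[i, ]
    lin <- which(tree$vessel_id == v$vessel_id)
    prow <- ((lin - 1L) %% nr) + 1L
    pcol <- ((lin - 1L) %/% nr) + 1L
    d_pix <- to_polar(cbind(prow, pcol), geometry)$d_mm

    if (v$label == "other_vessel") {
      la <- rep(1.5 + eye_offset, length(lin))
      pix_rows[[i]] <- data.frame(
        row = prow, col = pcol, vessel_id = v$vessel_id, label = v$label,
        d_mm = d_pix, log_amplitude = la, amplitude = exp(la)
      )
      next
    }

    pr <- presets[[v$hemifield]]
    slope <- if (v$label == "vein") pr$venous_slope else pr$arterial_slope
    target <- (if (v$label == "vein") pr$venous_mean_logamp
               else pr$arterial_mean_logamp) + eye_offset

    sel_l <- which(annulus_locus & gl$vessel_id == v$vessel_id &
                     gl$label == v$label)
    if (length(sel_l)) {
      # effective locus log amplitude before the intercept: log of the
      # cluster-mean of exp(slope * d) over the locus's labelled pixels
      m_l <- vapply(sel_l, function(j) {
        dp <- to_polar_linear(grid$pixels[[j]], nr, geometry)
        log(mean(exp(slope * dp)))
      }, numeric(1))
      intercept <- target - mean(m_l)
      locus_truth <- intercept + m_l
      d_l <- gl$d_mm[sel_l]
      slope_hat <- if (length(sel_l) >= 2 && stats::sd(d_l) > 0) {
        stats::cov(d_l, locus_truth) / stats::var(d_l)
      } else slope
      lrows[[i]] <- data.frame(
        locus_id = gl$locus_id[sel_l], vessel_id = v$vessel_id,
        label = v$label, hemifield = v$hemifield,
        d_mm = d_l, log_amplitude = locus_truth
      )
    } else {
      # vessel without annulus loci: calibrate on its annulus pixels
      ann <- d_pix >= 0.25 & d_pix <= 1.0
      base <- if (any(ann)) mean(slope * d_pix[ann]) else mean(slope * d_pix)
      intercept <- target - base
      locus_truth <- numeric(0)
      slope_hat <- slope
    }

    la <- intercept + slope * d_pix
    pix_rows[[i]] <- data.frame(
      row = prow, col = pcol, vessel_id = v$vessel_id, label = v$label,
      d_mm = d_pix, log_amplitude = la, amplitude = exp(la)
    )
    vrows[[i]] <- data.frame(
      vessel_id = v$vessel_id, label = v$label, hemifield = v$hemifield,
      group_id = pr$group_id,
      mean_logamp = if (length(locus_truth)) mean(locus_truth) else NA_real_,
      max_logamp = if (length(locus_truth)) max(locus_truth) else NA_real_,
      slope = slope_hat, preset_slope = slope,
      intercept = intercept, n_loci = length(locus_truth),
      stringsAsFactors = FALSE
    )
  }

  structure(
    list(
      pixels = do.call(rbind, pix_rows),
      loci = do.call(rbind, lrows),
      vessels = do.call(rbind, vrows),
      eye_offset = eye_offset
    ),
    class = "ppg_truth"
  )
}

# polar distance (mm) of linear pixel indices
to_polar_linear <- function(lin, nr, geometry) {
  prow <- ((lin - 1L) %% nr) + 1L
  pcol <- ((lin - 1L) %/% nr) + 1L
  to_polar(cbind(prow, pcol), geometry)$d_mm
}

#' @export
print.ppg_truth <- function(x, ...) {
  cat("ppg_truth:", nrow(x$pixels), "vessel pixels,",
      if (is.null(x$loci)) 0 else nrow(x$loci), "annulus loci,",
      nrow(x$vessels), "analysed vessels; eye offset",
      signif(x$eye_offset, 4), "log u\n")
  invisible(x)
}

#' Write ground truth tables as CSV
#' @param truth a `ppg_truth`.
#' @param dir output directory (created if needed); writes
#'   `truth_pixels.csv`, `truth_loci.csv`, `truth_vessels.csv`.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$pixels, file.path(dir, "truth_pixels.csv"), row.names = FALSE)
  if (!is.null(truth$loci)) {
    utils::write.csv(truth$loci, file.path(dir, "truth_loci.csv"), row.names = FALSE)
  }
  utils::write.csv(truth$vessels, file.path(dir, "truth_vessels.csv"), row.names = FALSE)
  invisible(dir)
}
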