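#' @title Segmentation maps
#' @description A segmentation map carries per-pixel tissue labels
#'   (background, disc, cup, other vessel, artery, vein), the optic-disc
#'   centre and spatial scale, and -- when vessels have been individuated --
#'   an integer vessel-id image plus a vessel table. Pixel coordinates are
#'   (row, col), 1-based, origin at the image top-left; "superior" retina is
#'   towards smaller row indices.
#' @name segmentation
NULL

# canonical label codes used in the label image
.ppg_legend <- c(
  background = 0L, disc = 1L, cup = 2L,
  other_vessel = 3L, artery = 4L, vein = 5L
)

#' Label legend for segmentation images
#' @return named integer vector mapping class names to pixel values.
#' @export
ppg_legend <- function() .ppg_legend

new_segmentation <- function(labels, disc_center, microns_per_pixel,
                             vessel_id = NULL, vessels = NULL) {
  stopifnot(is.matrix(labels))
  if (disc_center[1] < 1 || disc_center[1] > nrow(labels) ||
      disc_center[2] < 1 || disc_center[2] > ncol(labels)) {
    stop("disc_center must lie within the label image")
  }
  if (!all(unique(as.vector(labels)) %in% .ppg_legend)) {
    stop("label image holds values outside the legend")
  }
  structure(
    list(
      labels = labels,
      legend = .ppg_legend,
      disc_center = as.numeric(disc_center),
      microns_per_pixel = microns_per_pixel,
      vessel_id = vessel_id,
      vessels = vessels
    ),
    class = "ppg_segmentation"
  )
}

#' @export
print.ppg_segmentation <- function(x, ...) {
  cat("ppg_segmentation:", nrow(x$labels), "x", ncol(x$labels), "px,",
      x$microns_per_pixel, "um/px, disc centre (",
      x$disc_center[1], ",", x$disc_center[2], ")\n")
  tab <- table(factor(as.vector(x$labels), levels = x$legend,
                      labels = names(x$legend)))
  print(tab)
  if (!is.null(x$vessels)) {
    cat(nrow(x$vessels), "vessels individuated\n")
  }
  invisible(x)
}

#' Disc-centred geometry of a segmentation
#' @param seg a `ppg_segmentation`.
#' @return list with `disc_center` (row, col) and `microns_per_pixel`,
#'   class `ppg_geometry`.
#' @export
disc_geometry <- function(seg) {
  structure(
    list(disc_center = seg$disc_center,
         microns_per_pixel = seg$microns_per_pixel),
    class = "ppg_geometry"
  )
}

#' Generate a synthetic peripapillary vessel tree
#'
#' Draws a labelled segmentation image with an optic disc and cup and, per
#' hemifield, `n_vessels_per_type` straight arteries and veins radiating from
#' just outside the cup to beyond 1 mm from the disc centre, so the whole
#' 0.25--1 mm analysis annulus is covered. Vessel pixels override the
#' disc/cup labels where the vessel crosses them (vessels emerge from the cup
#' and run over the disc surface, as in fundus images). One thin
#' "other_vessel" path is added per hemifield; it is labelled but never
#' analysed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; vessel angles are drawn reproducibly from it.
#' @return a `ppg_segmentation` with `vessel_id` image and `vessels` table
#'   (`vessel_id`, `label`, `hemifield`, `angle_deg`, `width_px`).
#' @export
#' @examples
#' tree <- make_vessel_tree(sim_config(image_size = 400), seed = 1)
#' table(tree$vessels$label, tree$vessels$hemifield)
make_vessel_tree <- function(config, seed = config$seed) {
  n <- config$image_size
  ctr <- config$disc_center
  mmpp <- config$microns_per_pixel / 1000   # mm per pixel
  edge_mm <- min(ctr[1] - 1, n - ctr[1], ctr[2] - 1, n - ctr[2]) * mmpp
  if (edge_mm < config$vessel_outer_mm) {
    stop(
      "frame too small: vessels must reach ", config$vessel_outer_mm,
      " mm from the disc centre but only ", round(edge_mm, 3),
      " mm fit; the 0.25-1 mm annulus cannot be analysed"
    )
  }

  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  dx <- (cols - ctr[2]) * mmpp           # mm, +x to image right
  dy <- (ctr[1] - rows) * mmpp           # mm, +y towards superior (image top)
  rmm <- sqrt(dx^2 + dy^2)

  labels <- matrix(.ppg_legend[["background"]], n, n)
  labels[rmm <= config$disc_radius] <- .ppg_legend[["disc"]]
  labels[rmm <= config$cup_radius] <- .ppg_legend[["cup"]]

  # vessel angles: veins and arteries interleaved within each hemifield,
  # jittered so trees differ between eyes but paths stay straight rays
  set.seed(seed)
  k <- config$n_vessels_per_type
  vessel_plan <- list()
  for (hemi in c("superior", "inferior")) {
    base <- seq(40, 140, length.out = 2 * k + 2)[1 + seq_len(2 * k)]
    ang <- base + stats::runif(2 * k, -8, 8)
    if (hemi == "inferior") ang <- -ang
    lab <- rep(c("vein", "artery"), length.out = 2 * k)
    for (i in seq_len(2 * k)) {
      vessel_plan[[length(vessel_plan) + 1]] <-
        list(label = lab[i], hemifield = hemi, angle = ang[i])
    }
    # one untracked other_vessel per hemifield
    oa <- (if (hemi == "superior") 1 else -1) * stats::runif(1, 12, 30)
    vessel_plan[[length(vessel_plan) + 1]] <-
      list(label = "other_vessel", hemifield = hemi, angle = oa)
  }

  vessel_id <- matrix(0L, n, n)
  vtab <- list()
  vid <- 0L
  for (v in vessel_plan) {
    theta <- v$angle * pi / 180
    ux <- cos(theta); uy <- sin(theta)
    along <- dx * ux + dy * uy              # mm along the ray
    perp <- abs(-dx * uy + dy * ux)         # mm perpendicular distance
    width_mm <- switch(v$label,
      vein = config$vein_width_um,
      artery = config$artery_width_um,
      other_vessel = 0.6 * config$artery_width_um
    ) / 1000
    sel <- along >= config$vessel_inner_mm &
      along <= config$vessel_outer_mm &
      perp <= width_mm / 2
    vid <- vid + 1L
    labels[sel] <- .ppg_legend[[v$label]]
    vessel_id[sel] <- vid
    vtab[[vid]] <- data.frame(
      vessel_id = vid, label = v$label, hemifield = v$hemifield,
      angle_deg = v$angle,
      width_px = width_mm / mmpp,
      stringsAsFactors = FALSE
    )
  }
  vessels <- do.call(rbind, vtab)

  seg <- new_segmentation(labels, ctr, config$microns_per_pixel,
                          vessel_id = vessel_id, vessels = vessels)

  # postcondition: every analysed vessel must reach past 1 mm and into the
  # annulus, and each hemifield holds at least one artery and one vein
  for (i in seq_len(nrow(vessels))) {
    if (vessels$label[i] == "other_vessel") next
    r <- rmm[vessel_id == vessels$vessel_id[i]]
    if (!length(r) || max(r) < 1.0 || min(r) > 0.25) {
      stop("vessel ", vessels$vessel_id[i], " does not span the annulus")
    }
  }
  for (hemi in c("superior", "inferior")) {
    hv <- vessels[vessels$hemifield == hemi, "label"]
    if (!all(c("artery", "vein") %in% hv)) {
      stop("hemifield ", hemi, " lacks an artery or a vein")
    }
  }
  seg
}

#' Individuate vessels by connected components
#'
#' For segmentations lacking a vessel-id image (e.g. read from an external
#' labelling tool), assigns each connected component of the artery mask and
#' of the vein mask a distinct vessel id, and builds the vessel table. The
#' hemifield of a component is taken from the sign of its loci's mean angle
#' about the disc centre.
#'
#' @param seg a `ppg_segmentation`.
#' @return the segmentation with `vessel_id` and `vessels` filled in.
#' @export
label_vessels <- function(seg) {
  vessel_id <- matrix(0L, nrow(seg$labels), ncol(seg$labels))
  vtab <- list()
  offset <- 0L
  for (lab in c("vein", "artery", "other_vessel")) {
    mask <- seg$labels == seg$legend[[lab]]
    if (!any(mask)) next
    comp <- EBImage::bwlabel(mask)
    ids <- sort(unique(comp[comp > 0]))
    for (i in ids) {
      sel <- comp == i
      offset <- offset + 1L
      vessel_id[sel] <- offset
      pix <- which(sel, arr.ind = TRUE)
      pol <- to_polar(pix, disc_geometry(seg))
      ang <- mean(pol$angle_deg)
      vtab[[offset]] <- data.frame(
        vessel_id = offset, label = lab,
        hemifield = if (ang > 0) "superior" else "inferior",
        angle_deg = ang, width_px = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  seg$vessel_id <- vessel_id
  seg$vessels <- do.call(rbind, vtab)
  seg
}

#' Write / read a segmentation as an indexed PNG with a JSON sidecar
#'
#' The label image is written as an 8-bit grayscale PNG holding the legend's
#' integer codes; the sidecar (`<path>.json`) records the legend, disc
#' centre, spatial scale, and the vessel table. The vessel-id image, when
#' present, is written alongside as `<path>_vesselid.png`.
#'
#' @param seg a `ppg_segmentation`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  png::writePNG(seg$labels / 255, path)
  sidecar <- list(
    legend = as.list(seg$legend),
    disc_center = seg$disc_center,
    microns_per_pixel = seg$microns_per_pixel,
    vessels = seg$vessels
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(seg$vessel_id)) {
    png::writePNG(seg$vessel_id / 255, paste0(sub("\\.png$", "", path), "_vesselid.png"))
  }
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  labels <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vid_path <- paste0(sub("\\.png$", "", path), "_vesselid.png")
  vessel_id <- NULL
  if (file.exists(vid_path)) {
    vi <- png::readPNG(vid_path)
    if (length(dim(vi)) == 3) vi <- vi[, , 1]
    vessel_id <- matrix(as.integer(round(vi * 255)), nrow(vi), ncol(vi))
  }
  vessels <- sidecar$vessels
  if (!is.null(vessels) && !is.data.frame(vessels)) vessels <- as.data.frame(vessels)
  new_segmentation(labels, unlist(sidecar$disc_center),
                   sidecar$microns_per_pixel,
                   vessel_id = vessel_id, vessels = vessels)
}
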