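#' Tile the vessel mask into analysis loci
#'
#' Lays a fixed grid of `cluster x cluster` pixel blocks over the image
#' (anchored at pixel (1,1), stride equal to the cluster size; at the default
#' 6 micron scale a 5x5 block is one 30x30 micron locus) and, for each target
#' vessel class, records every block containing pixels of that class. A block
#' is a valid locus for a class when at least `min_fraction` of its pixels
#' carry that class label. The locus centre is the block's central pixel.
#'
#' This tiling is purely a function of the segmentation, so the synthetic
#' ground-truth generator and the analysis pipeline share it.
#'
#' @param seg a `ppg_segmentation` with `vessel_id` filled in (see
#'   [label_vessels()]).
#' @param labels vessel classes to tile (default artery and vein).
#' @param cluster block side length in pixels (default 5).
#' @param min_fraction minimum fraction of block pixels carrying the class
#'   label for the locus to be valid (default 0.6).
#' @return list with `loci` (data.frame: `locus_id`, `center_row`,
#'   `center_col`, `label`, `vessel_id`, `n_label_pixels`, `fraction`,
#'   `valid`) and `pixels` (list of linear pixel indices per locus, the
#'   block's pixels carrying the class label).
#' @export
locus_grid <- function(seg, labels = c("artery", "vein"), cluster = 5,
                       min_fraction = 0.6) {
  lab_img <- seg$labels
  nr <- nrow(lab_img); nc <- ncol(lab_img)
  nbr <- nr %/% cluster; nbc <- nc %/% cluster
  if (nbr < 1 || nbc < 1) stop("image smaller than one cluster")
  if (is.null(seg$vessel_id)) stop("segmentation lacks vessel ids; run label_vessels() first")

  loci <- list(); pixels <- list(); lid <- 0L
  for (lab in labels) {
    code <- seg$legend[[lab]]
    lin <- which(lab_img == code)
    if (!length(lin)) next
    row <- ((lin - 1L) %% nr) + 1L
    col <- ((lin - 1L) %/% nr) + 1L
    inside <- row <= nbr * cluster & col <= nbc * cluster
    lin <- lin[inside]; row <- row[inside]; col <- col[inside]
    if (!length(lin)) next
    br <- (row - 1L) %/% cluster
    bc <- (col - 1L) %/% cluster
    block <- br + nbr * bc
    by_block <- split(lin, block)
    for (b in names(by_block)) {
      bi <- as.integer(b)
      pix <- by_block[[b]]
      n <- length(pix)
      vid_tab <- tabulate(seg$vessel_id[pix])
      lid <- lid + 1L
      loci[[lid]] <- data.frame(
        locus_id = lid,
        center_row = (bi %% nbr) * cluster + (cluster + 1L) %/% 2,
        center_col = (bi %/% nbr) * cluster + (cluster + 1L) %/% 2,
        label = lab,
        vessel_id = if (length(vid_tab)) which.max(vid_tab) else NA_integer_,
        n_label_pixels = n,
        fraction = n / cluster^2,
        valid = n / cluster^2 >= min_fraction,
        stringsAsFactors = FALSE
      )
      pixels[[lid]] <- pix
    }
  }
  if (!lid) stop("no vessel pixels found for labels: ", paste(labels, collapse = ", "))
  list(loci = do.call(rbind, loci), pixels = pixels, cluster = cluster)
}

#' Extract per-locus densitometry time series
#'
#' Applies [locus_grid()] to the segmentation and reduces the video to one
#' time series per locus: the per-frame mean green intensity over the block
#' pixels carrying the locus's vessel label.
#'
#' @param video a `ppg_video` (see [read_stack()]), single channel.
#' @param seg a `ppg_segmentation` sharing the video's dimensions.
#' @inheritParams locus_grid
#' @return a `locus_set`: list with `loci` (as in [locus_grid()]), `series`
#'   (matrix, loci x frames), and `timestamps` (seconds).
#' @export
assemble_loci <- function(video, seg, labels = c("artery", "vein"),
                          cluster = 5, min_fraction = 0.6) {
  dims <- dim(video$frames)
  if (dims[1] != nrow(seg$labels) || dims[2] != ncol(seg$labels)) {
    stop("video frames and segmentation have different dimensions")
  }
  grid <- locus_grid(seg, labels = labels, cluster = cluster,
                     min_fraction = min_fraction)
  nt <- dims[3]
  fm <- matrix(video$frames, dims[1] * dims[2], nt)
  pix <- unlist(grid$pixels, use.names = FALSE)
  grp <- rep.int(seq_along(grid$pixels), lengths(grid$pixels))
  sums <- rowsum(fm[pix, , drop = FALSE], grp, reorder = TRUE)
  series <- sums / grid$loci$n_label_pixels
  structure(
    list(loci = grid$loci, series = series,
         timestamps = video$timestamps, cluster = cluster),
    class = "locus_set"
  )
}

#' @export
print.locus_set <- function(x, ...) {
  cat("locus_set:", nrow(x$loci), "loci (", sum(x$loci$valid), "valid ) x",
      length(x$timestamps), "frames\n")
  print(table(x$loci$label, x$loci$valid))
  invisible(x)
}
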