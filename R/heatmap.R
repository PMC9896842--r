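#' Render a pulse-amplitude heat map
#'
#' Paints each locus's 5x5 block with a colour encoding its raw (pre-log)
#' pulse amplitude clipped to the display scale (default 0--40 arbitrary
#' units, the conventional display range), composited over a background
#' frame, and writes the result as a PNG with an embedded colour-bar legend.
#' Heat maps display raw amplitude for visual review; all statistics run on
#' log amplitude.
#'
#' @param map an `amplitude_map` (annulus-filtered or not), non-empty.
#' @param background a background frame (matrix, intensity units).
#' @param path output PNG path.
#' @param scale display range `c(min, max)` in amplitude units.
#' @param cluster block size painted around each locus centre.
#' @param palette colour ramp function or vector of colours low-to-high.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(map, background, path, scale = c(0, 40),
                           cluster = 5,
                           palette = c("#000080", "#0080FF", "#00FF80",
                                       "#FFFF00", "#FF8000", "#FF0000")) {
  if (!nrow(map)) stop("amplitude map is empty; nothing to render")
  ramp <- grDevices::colorRamp(palette)
  bg <- background - min(background)
  if (max(bg) > 0) bg <- bg / max(bg)
  nr <- nrow(bg); nc <- ncol(bg)
  img <- array(rep(bg, 3), dim = c(nr, nc, 3))
  half <- cluster %/% 2
  amp <- pmin(pmax(map$amplitude, scale[1]), scale[2])
  frac <- (amp - scale[1]) / diff(scale)
  cols <- ramp(frac) / 255
  for (i in seq_len(nrow(map))) {
    rr <- max(1, map$center_row[i] - half):min(nr, map$center_row[i] + half)
    cc <- max(1, map$center_col[i] - half):min(nc, map$center_col[i] + half)
    for (ch in 1:3) img[rr, cc, ch] <- cols[i, ch]
  }
  # embedded legend: vertical colour bar along the right edge
  bar_w <- max(4L, round(nc * 0.02))
  bar_r <- round(seq(nr * 0.1, nr * 0.9, length.out = 200))
  bar_frac <- seq(1, 0, length.out = length(bar_r))
  bar_cols <- ramp(bar_frac) / 255
  for (k in seq_along(bar_r)) {
    for (ch in 1:3) {
      img[bar_r[k], (nc - bar_w + 1):nc, ch] <- bar_cols[k, ch]
    }
  }
  grDevices::png(path, width = nc + 80, height = nr, res = 96)
  op <- graphics::par(mar = c(0, 0, 0, 4))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot(0, 0, type = "n", xlim = c(0, nc), ylim = c(nr, 0),
                 axes = FALSE, xlab = "", ylab = "", xaxs = "i", yaxs = "i")
  graphics::rasterImage(img, 0, nr, nc, 0)
  graphics::mtext(sprintf("%g", scale[2]), side = 4, las = 1,
                  at = nr * 0.1, line = 0.5, cex = 0.8)
  graphics::mtext(sprintf("%g", scale[1]), side = 4, las = 1,
                  at = nr * 0.9, line = 0.5, cex = 0.8)
  graphics::mtext("amplitude (arb. u)", side = 4, at = nr * 0.5,
                  line = 2, cex = 0.8)
  invisible(path)
}
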