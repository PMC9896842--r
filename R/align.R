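#' Rigid frame alignment by integer-pixel cross-correlation
#'
#' Translates each frame by the integer-pixel shift maximising its circular
#' cross-correlation (computed via FFT) with a reference frame. Integer
#' rigid translation preserves raw densitometric values, which sub-pixel
#' interpolation would smooth. Border pixels introduced by shifting are set
#' to `NA` and flagged invalid. Frames whose best shift exceeds `cap` pixels
#' are left unshifted and flagged excluded.
#'
#' @param video a `ppg_video` with at least two frames.
#' @param reference reference frame index (default 1).
#' @param cap maximum allowed shift magnitude in pixels (default 20).
#' @return list with `video` (aligned `ppg_video`) and `shifts` (data.frame:
#'   `frame`, `d_row`, `d_col`, `excluded`).
#' @export
align_frames <- function(video, reference = 1, cap = 20) {
  d <- dim(video$frames)
  if (d[3] < 2) stop("alignment needs at least two frames")
  ref <- video$frames[, , reference]
  fr <- stats::fft(ref)
  nr <- d[1]; nc <- d[2]
  out <- video$frames
  shifts <- data.frame(frame = seq_len(d[3]), d_row = 0L, d_col = 0L,
                       excluded = FALSE)
  wrap <- function(idx, n) ifelse(idx > n / 2, idx - n, idx)
  for (i in seq_len(d[3])) {
    if (i == reference) next
    cc <- Re(stats::fft(fr * Conj(stats::fft(video$frames[, , i])),
                        inverse = TRUE))
    peak <- which.max(cc)
    pr <- ((peak - 1) %% nr)
    pc <- ((peak - 1) %/% nr)
    dr <- wrap(pr, nr)
    dc <- wrap(pc, nc)
    if (max(abs(dr), abs(dc)) > cap) {
      shifts$excluded[i] <- TRUE
      next
    }
    shifts$d_row[i] <- dr
    shifts$d_col[i] <- dc
    out[, , i] <- shift_frame(video$frames[, , i], dr, dc)
  }
  list(video = new_video(out, video$timestamps, video$channel),
       shifts = shifts)
}

# translate a matrix by (dr, dc), padding uncovered borders with NA
shift_frame <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}
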