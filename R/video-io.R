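#' @title Video sequences
#' @description A `ppg_video` holds an ordered stack of single-channel
#'   frames as a 3-D array `[row, col, frame]`, per-frame timestamps in
#'   seconds (strictly increasing), and a channel tag. Intensities are
#'   arbitrary densitometric units; on disk frames are stored as 16-bit
#'   grayscale scaled by 1/255 into the unit interval.
#' @name video
NULL

.ppg_intensity_scale <- 255  # on-disk unit interval maps to 0..255 units

new_video <- function(frames, timestamps, channel = "green") {
  stopifnot(length(dim(frames)) == 3)
  if (length(timestamps) != dim(frames)[3]) {
    stop("one timestamp per frame required")
  }
  if (is.unsorted(timestamps, strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 channel = channel),
            class = "ppg_video")
}

#' @export
print.ppg_video <- function(x, ...) {
  d <- dim(x$frames)
  cat("ppg_video:", d[3], "frames of", d[1], "x", d[2], "px (",
      x$channel, "), t =", round(min(x$timestamps), 3), "..",
      round(max(x$timestamps), 3), "s\n")
  invisible(x)
}

#' Read a frame stack
#'
#' Reads either a multi-page 16-bit grayscale TIFF or a directory of
#' numbered PNG/TIFF frames (lexicographic order). Timestamps come from a
#' JSON sidecar (`<stack>.json`, fields `fps` or `timestamps`) when present,
#' else from the `fps` argument. All frames must share dimensions.
#'
#' @param path multi-page TIFF file, or directory of numbered frames.
#' @param fps frames per second, required when no timing sidecar exists.
#' @return a `ppg_video`.
#' @export
read_stack <- function(path, fps = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             full.names = TRUE, ignore.case = TRUE))
    if (!length(files)) stop("no PNG/TIFF frames found in ", path)
    read1 <- function(f) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
        png::readPNG(f)
      } else {
        tiff::readTIFF(f)
      }
      if (length(dim(img)) == 3) img <- img[, , 1]
      img
    }
    frames <- lapply(files, read1)
    sidecar <- file.path(path, "stack.json")
  } else {
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    frames <- lapply(frames, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
    sidecar <- paste0(sub("\\.(tif|tiff)$", "", path, ignore.case = TRUE), ".json")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("frames have mixed dimensions; a stack must be homogeneous")
  }
  nt <- length(frames)
  arr <- array(unlist(frames, use.names = FALSE),
               dim = c(dims[1, 1], dims[2, 1], nt)) * .ppg_intensity_scale
  ts <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$timestamps)) ts <- meta$timestamps
    else if (!is.null(meta$fps)) ts <- (seq_len(nt) - 1) / meta$fps
  }
  if (is.null(ts)) {
    if (is.null(fps)) stop("no timing sidecar found; supply fps")
    ts <- (seq_len(nt) - 1) / fps
  }
  new_video(arr, ts)
}

#' Write a frame stack as a multi-page 16-bit TIFF
#'
#' Intensities are scaled into \[0, 1\] by 1/255 before writing (values must
#' lie in \[0, 255\]); a JSON sidecar records the timestamps.
#'
#' @param video a `ppg_video`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(video, path) {
  nt <- dim(video$frames)[3]
  pages <- lapply(seq_len(nt), function(i) {
    m <- video$frames[, , i] / .ppg_intensity_scale
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(timestamps = video$timestamps, channel = video$channel),
    paste0(sub("\\.(tif|tiff)$", "", path, ignore.case = TRUE), ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Extract the green channel
#'
#' Green-channel densitometry tracks haemoglobin light absorption, so all
#' analysis runs on the green plane. RGB(A) input is reduced to its second
#' plane; single-channel input passes through unchanged (the operation is
#' idempotent). Two-channel input is rejected as malformed.
#'
#' @param video a `ppg_video` whose `frames` are either a 3-D single-channel
#'   stack or a 4-D array `[row, col, channel, frame]` with >= 3 channels.
#' @return a single-channel `ppg_video` with `channel = "green"`.
#' @export
extract_green <- function(video) {
  d <- dim(video$frames)
  if (length(d) == 3) {
    video$channel <- "green"
    return(video)
  }
  if (length(d) == 4) {
    if (d[3] < 3) stop("two-channel input: cannot identify a green plane")
    return(new_video(video$frames[, , 2, , drop = TRUE], video$timestamps,
                     channel = "green"))
  }
  stop("frames must be a 3-D (grayscale) or 4-D (multichannel) array")
}
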