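#' Cardiac timing from pulse-oximeter beeps
#'
#' Builds the cardiac timing object from beep timestamps (one beep at each
#' cycle start). The period estimate is the mean of successive beep
#' intervals and cycle bounds pair consecutive beeps.
#'
#' @param beep_times beep timestamps in seconds, strictly increasing, >= 2.
#' @return list of class `ppg_timing` with `beep_times`, `period_estimate`
#'   and `cycle_bounds` (two-column matrix of start/end seconds).
#' @export
#' @examples
#' cardiac_timing(c(0, 0.8, 1.7))$period_estimate  # 0.85
cardiac_timing <- function(beep_times) {
  if (length(beep_times) < 2) {
    stop("at least two beeps are needed to estimate the cardiac period")
  }
  if (is.unsorted(beep_times, strictly = TRUE)) {
    stop("beep_times must be strictly increasing")
  }
  bounds <- cbind(start = beep_times[-length(beep_times)],
                  end = beep_times[-1])
  structure(
    list(beep_times = as.numeric(beep_times),
         period_estimate = mean(diff(beep_times)),
         cycle_bounds = bounds),
    class = "ppg_timing"
  )
}

#' Estimated cardiac period
#' @param timing a `ppg_timing`.
#' @return period in seconds (mean successive beep interval).
#' @export
estimate_period <- function(timing) {
  timing$period_estimate
}

#' Trim a recording to the first n complete cardiac cycles
#'
#' Restricts the stack to frames with timestamps in
#' `[first beep, first beep + n * period)`, the analysis window of `n`
#' complete cycles guided by the oximeter audio.
#'
#' @param video a `ppg_video`.
#' @param timing a `ppg_timing`.
#' @param n number of cycles to keep (default 3).
#' @return the trimmed `ppg_video`.
#' @export
trim_cycles <- function(video, timing, n = 3) {
  available <- length(timing$beep_times) - 1
  if (available < n) {
    stop("recording holds only ", available, " complete cycles; ", n,
         " requested")
  }
  t0 <- timing$beep_times[1]
  t1 <- t0 + n * timing$period_estimate
  keep <- video$timestamps >= t0 & video$timestamps < t1
  if (!any(keep)) stop("no frames fall inside the requested cycles")
  new_video(video$frames[, , keep, drop = FALSE],
            video$timestamps[keep], video$channel)
}

#' Read / write beep timing CSV
#'
#' The on-disk contract is a CSV with a single `beep_time_s` column of
#' seconds (decoding the oximeter audio track is out of scope; timestamps
#' are produced upstream).
#'
#' @param path CSV path.
#' @return [read_timing()]: a `ppg_timing`.
#' @export
read_timing <- function(path) {
  tab <- utils::read.csv(path)
  if (!"beep_time_s" %in% names(tab)) stop("timing CSV needs a beep_time_s column")
  cardiac_timing(tab$beep_time_s)
}

#' @rdname read_timing
#' @param timing a `ppg_timing` to write.
#' @export
write_timing <- function(timing, path) {
  utils::write.csv(data.frame(beep_time_s = timing$beep_times), path,
                   row.names = FALSE)
  invisible(path)
}
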