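#' PET acquisition frame schedules
#'
#' A frame schedule is an ordered set of acquisition intervals
#' `(start, end)` in minutes since injection. Whole-body protocols on
#' limited-field-of-view scanners leave rest gaps between bed passes, so
#' intervals need not be contiguous, but they must be strictly increasing
#' and non-overlapping.
#'
#' @param start,end Numeric vectors of equal length: frame start and end
#'   times in minutes since injection.
#'
#' @return An object of class `frame_schedule`: a data.frame with columns
#'   `start_min` and `end_min`.
#'
#' @examples
#' # 7-pass whole-body protocol with 4-min rest gaps
#' schedule_t807()
#' @export
frame_schedule <- function(start, end) {
  if (length(start) != length(end)) {
    stop("frame start and end vectors must have equal length")
  }
  if (length(start) == 0L) stop("frame schedule has no frames")
  if (!all(is.finite(start)) || !all(is.finite(end))) {
    stop("frame times must be finite")
  }
  if (any(start < 0)) stop("frame start times must be >= 0 (minutes since injection)")
  if (any(end <= start)) {
    bad <- which(end <= start)[1L]
    stop(sprintf("frame %d has end <= start (%g <= %g)", bad, end[bad], start[bad]))
  }
  if (length(start) > 1L && any(start[-1L] < end[-length(end)])) {
    bad <- which(start[-1L] < end[-length(end)])[1L]
    stop(sprintf("frames %d and %d overlap or are out of order", bad, bad + 1L))
  }
  obj <- data.frame(start_min = as.numeric(start), end_min = as.numeric(end))
  class(obj) <- c("frame_schedule", "data.frame")
  obj
}

#' @describeIn frame_schedule The 7-frame whole-body schedule used for
#'   \eqn{^{18}}F-T807: 0-8, 12-20, 24-32, 40-48, 60-68, 84-92, 112-120 min.
#' @export
schedule_t807 <- function() {
  frame_schedule(c(0, 12, 24, 40, 60, 84, 112), c(8, 20, 32, 48, 68, 92, 120))
}

#' @describeIn frame_schedule The 5-frame whole-body schedule used for
#'   \eqn{^{18}}F-Mefway: 0-16, 20-36, 40-56, 60-84, 90-114 min.
#' @export
schedule_mefway <- function() {
  frame_schedule(c(0, 20, 40, 60, 90), c(16, 36, 56, 84, 114))
}

#' @describeIn frame_schedule `n` contiguous uniform frames covering
#'   `[0, t_end_min]`; used for dense-sampling checks.
#' @param n Number of uniform frames.
#' @param t_end_min End of the covered interval, minutes.
#' @export
schedule_uniform <- function(n, t_end_min = 120) {
  stopifnot(n >= 1, t_end_min > 0)
  edges <- seq(0, t_end_min, length.out = n + 1L)
  frame_schedule(edges[-(n + 1L)], edges[-1L])
}

#' Frame midpoint times
#'
#' Each multi-minute acquisition frame is reduced to its midpoint
#' `(start + end) / 2` for integration; organ curves are treated as point
#' series at these times.
#'
#' @param schedule A [frame_schedule()].
#' @return Numeric vector of midpoint times in minutes, strictly increasing.
#' @examples
#' frame_midpoints(schedule_mefway())  # 8 28 48 72 102
#' @export
frame_midpoints <- function(schedule) {
  if (!inherits(schedule, "frame_schedule")) {
    schedule <- frame_schedule(schedule[[1L]], schedule[[2L]])
  }
  if (nrow(schedule) == 0L) stop("frame schedule has no frames")
  (schedule$start_min + schedule$end_min) / 2
}
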