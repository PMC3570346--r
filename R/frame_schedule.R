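#' Construct a PET frame schedule
#'
#' A frame schedule records how list-mode coincidence data were histogrammed
#' into consecutive time frames. Frames must be contiguous (each frame starts
#' where the previous one ends) and have strictly positive durations.
#'
#' @param frame_durations_s Numeric vector of frame durations in seconds.
#' @param start_s Scan start time of the first frame in seconds (default 0).
#'
#' @return A tibble of class `frame_schedule` with columns
#'   `frame` (index), `start_s`, `dur_s`, `end_s`, and the derived
#'   `mid_min` (frame midpoint in minutes from scan start).
#' @examples
#' sched <- frame_schedule(c(rep(15, 8), rep(20, 6), rep(60, 6)))
#' sched
#' @export
frame_schedule <- function(frame_durations_s, start_s = 0) {
  if (length(frame_durations_s) < 1 || any(!is.finite(frame_durations_s)) ||
      any(frame_durations_s <= 0)) {
    abort("frame durations must be finite and strictly positive")
  }
  starts <- start_s + cumsum(c(0, frame_durations_s[-length(frame_durations_s)]))
  out <- tibble(
    frame = seq_along(frame_durations_s),
    start_s = starts,
    dur_s = as.numeric(frame_durations_s),
    end_s = starts + frame_durations_s,
    mid_min = (starts + frame_durations_s / 2) / 60
  )
  class(out) <- c("frame_schedule", class(out))
  out
}

#' Default dynamic acquisition schedule
#'
#' The 60-min dynamic schedule used throughout this package: 8 x 15 s,
#' 6 x 20 s, 6 x 60 s, 3 x 180 s and 5 x 500 s — 28 consecutive frames
#' spanning 3640 s, with frame widths growing as count rates fall.
#'
#' @return A [frame_schedule()] tibble with 28 rows.
#' @export
default_frame_schedule <- function() {
  frame_schedule(c(rep(15, 8), rep(20, 6), rep(60, 6), rep(180, 3), rep(500, 5)))
}

#' Default arterial blood-sampling times
#'
#' Samples every 15 s for the first 4 min after the start of tracer
#' infusion, then at 10, 20, 30 and 50 min.
#'
#' @return Numeric vector of sampling times in minutes.
#' @export
default_sample_times <- function() {
  c(seq(0.25, 4, by = 0.25), 10, 20, 30, 50)
}

assert_schedule <- function(schedule) {
  if (!inherits(schedule, "frame_schedule")) {
    abort("`schedule` must be a frame_schedule object")
  }
  invisible(schedule)
}

schedule_end_min <- function(schedule) max(schedule$end_s) / 60
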