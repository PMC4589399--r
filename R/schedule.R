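#' Construct a frame schedule
#'
#' @param starts frame start times in seconds; the first frame starts at 0.
#' @param durations frame lengths in seconds.  If `starts` is missing the
#'   schedule is built contiguously from `durations` alone.
#' @return a [FrameSchedule-class].
#' @examples
#' frameSchedule(durations = c(1, 1, 2, 5))
#' @export
frameSchedule <- function(starts, durations) {
  durations <- as.numeric(durations)
  if (missing(starts)) starts <- cumsum(c(0, durations[-length(durations)]))
  new("FrameSchedule", starts = as.numeric(starts), durations = durations)
}

#' The 28-frame dynamic mouse acquisition protocol
#'
#' The bolus-chasing framing used throughout this package as the default
#' acquisition: 2 x 1.5 s, 10 x 0.5 s, 8 x 5 s, then single frames of 20,
#' 30, 75, 120, 150, 400, 600, 750 and 900 s — 28 frames totalling 3093 s.
#' The total duration is validated at construction.
#'
#' @return a [FrameSchedule-class] with 28 frames.
#' @examples
#' totalDuration(mouseDynamicSchedule())
#' @export
mouseDynamicSchedule <- function() {
  d <- c(rep(1.5, 2), rep(0.5, 10), rep(5, 8),
         20, 30, 75, 120, 150, 400, 600, 750, 900)
  sched <- frameSchedule(durations = d)
  stopifnot(abs(totalDuration(sched) - 3093) < 1e-9)
  sched
}

#' @rdname dynFDG-accessors
#' @export
setMethod("frameStarts", "FrameSchedule", function(object) object@starts)

#' @rdname dynFDG-accessors
#' @export
setMethod("frameDurations", "FrameSchedule", function(object) object@durations)

#' @rdname dynFDG-accessors
#' @export
setMethod("frameMids", "FrameSchedule",
  function(object) object@starts + object@durations / 2)

#' @rdname dynFDG-accessors
#' @export
setMethod("nFrames", "FrameSchedule", function(object) length(object@starts))

#' @rdname dynFDG-accessors
#' @export
setMethod("totalDuration", "FrameSchedule",
  function(object) sum(object@durations))

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, 0-%g s\n",
              nFrames(object), totalDuration(object)))
})

#' Construct a time-activity curve
#'
#' @param schedule a [FrameSchedule-class].
#' @param activity frame-averaged activity concentration, MBq/mL.
#' @return a [TimeActivityCurve-class].
#' @export
timeActivityCurve <- function(schedule, activity) {
  new("TimeActivityCurve", schedule = schedule, activity = as.numeric(activity))
}

#' @rdname dynFDG-accessors
#' @export
setMethod("schedule", "TimeActivityCurve", function(object) object@schedule)

#' @rdname dynFDG-accessors
#' @export
setMethod("activity", "TimeActivityCurve", function(object) object@activity)

#' @rdname dynFDG-accessors
#' @export
setMethod("frameMids", "TimeActivityCurve",
  function(object) frameMids(object@schedule))

#' @rdname dynFDG-accessors
#' @export
setMethod("nFrames", "TimeActivityCurve",
  function(object) nFrames(object@schedule))

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve: %d frames, peak %.4g MBq/mL\n",
              nFrames(object), max(object@activity)))
})

#' @describeIn timeActivityCurve coerce a TAC to a data.frame with columns
#'   `frame_start_s`, `frame_duration_s`, `concentration_MBq_per_mL`.
#' @param x a [TimeActivityCurve-class].
#' @param row.names,optional,... passed on for S3 compatibility (unused).
#' @export
as.data.frame.TimeActivityCurve <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(frame_start_s = frameStarts(x@schedule),
             frame_duration_s = frameDurations(x@schedule),
             concentration_MBq_per_mL = x@activity)
}

#' Piecewise-linear interpolant of a time-activity curve
#'
#' Returns a vectorized function of time (seconds) that is 0 at t = 0,
#' passes through the frame values at the frame mid-times, and holds the
#' last frame value constant beyond the final mid-time.  This is the input
#' representation used by the model fit and the Patlak analysis.
#'
#' @param tac a [TimeActivityCurve-class].
#' @return function(t) -> MBq/mL.
#' @export
tacInterpolant <- function(tac) {
  mids <- frameMids(tac@schedule)
  xs <- c(0, mids)
  ys <- c(0, tac@activity)
  function(t) {
    out <- stats::approx(xs, ys, xout = pmax(t, 0), rule = 2)$y
    out[t < 0] <- 0
    out
  }
}
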