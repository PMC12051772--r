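#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule is the temporal grid of a dynamic scan: one start time and
#' one duration per reconstructed frame, both in seconds. Frames must be
#' contiguous (each frame starts where the previous one ends) and
#' non-overlapping.
#'
#' @param start_s Numeric vector of frame start times (s).
#' @param duration_s Numeric vector of frame durations (s), same length.
#' @return An object of class `frame_schedule`.
#' @seealso [standard_schedule()] for the two built-in 90-min schedules.
#' @export
frame_schedule <- function(start_s, duration_s) {
  if (!is.numeric(start_s) || !is.numeric(duration_s))
    stop("`start_s` and `duration_s` must be numeric", call. = FALSE)
  if (length(start_s) != length(duration_s) || length(start_s) < 1L)
    stop("`start_s` and `duration_s` must have equal positive length", call. = FALSE)
  if (any(duration_s <= 0))
    stop("all frame durations must be > 0", call. = FALSE)
  if (length(start_s) > 1L && any(diff(start_s) <= 0))
    stop("frame starts must be strictly increasing", call. = FALSE)
  n <- length(start_s)
  if (n > 1L) {
    gap <- start_s[-1L] - (start_s[-n] + duration_s[-n])
    if (any(abs(gap) > 1e-6))
      stop("frames must be contiguous and non-overlapping", call. = FALSE)
  }
  structure(list(start_s = as.numeric(start_s),
                 duration_s = as.numeric(duration_s)),
            class = "frame_schedule")
}

#' Built-in 90-minute dynamic acquisition schedules
#'
#' Two reconstruction schedules are supported, named after the acquiring
#' site: `"WCM"` (32 frames: 6 x 10 s, 4 x 30 s, 3 x 60 s, 2 x 120 s,
#' 5 x 240 s, 12 x 300 s) and `"JHMI"` (30 frames: 4 x 15 s, then the same
#' tail). Both span 5400 s = 90 min.
#'
#' @param site `"WCM"` or `"JHMI"`.
#' @return A [frame_schedule()].
#' @export
standard_schedule <- function(site = c("WCM", "JHMI")) {
  site <- match.arg(site)
  durs <- switch(site,
    WCM  = c(rep(10, 6), rep(30, 4), rep(60, 3), rep(120, 2),
             rep(240, 5), rep(300, 12)),
    JHMI = c(rep(15, 4), rep(30, 4), rep(60, 3), rep(120, 2),
             rep(240, 5), rep(300, 12)))
  starts <- c(0, cumsum(durs)[-length(durs)])
  frame_schedule(starts, durs)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.1f min total\n",
              n_frames(x), total_duration(x) / 60))
  invisible(x)
}

#' Number of frames in a schedule
#' @param schedule A [frame_schedule()].
#' @return Integer frame count.
#' @export
n_frames <- function(schedule) length(schedule$start_s)

#' Total scan duration (s)
#' @param schedule A [frame_schedule()].
#' @return Scan length in seconds.
#' @export
total_duration <- function(schedule) {
  n <- n_frames(schedule)
  schedule$start_s[n] + schedule$duration_s[n]
}

#' Frame midpoints
#'
#' The single representative time of each frame, `start + duration/2`. All
#' package code that needs one time per frame (Logan transforms,
#' interpolation across schedules) uses these midpoints.
#'
#' @param schedule A [frame_schedule()].
#' @param unit `"s"` or `"min"`.
#' @return Numeric vector of midpoints.
#' @export
frame_midpoints <- function(schedule, unit = c("s", "min")) {
  unit <- match.arg(unit)
  m <- schedule$start_s + schedule$duration_s / 2
  if (unit == "min") m / 60 else m
}

#' Read / write a frame-schedule sidecar CSV
#'
#' The sidecar has columns `frame_index,start_s,duration_s`, one row per
#' frame.
#'
#' @param schedule A [frame_schedule()].
#' @param path File path.
#' @return `read_schedule` returns a [frame_schedule()]; `write_schedule`
#'   returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  df <- data.frame(frame_index = seq_len(n_frames(schedule)),
                   start_s = schedule$start_s,
                   duration_s = schedule$duration_s)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path)
  req <- c("frame_index", "start_s", "duration_s")
  if (!all(req %in% names(df)))
    stop("schedule CSV must have columns frame_index,start_s,duration_s",
         call. = FALSE)
  df <- df[order(df$frame_index), ]
  frame_schedule(df$start_s, df$duration_s)
}
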