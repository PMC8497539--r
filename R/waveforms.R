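#' Parametric displacement waveform of one swallow
#'
#' A swallow briefly elevates the larynx, which drags the overlying neck skin
#' (and any sticker attached to it) upward along the image y-axis and back.
#' The waveform models that vertical displacement as a single pulse that is
#' zero outside its time window and reaches `peak_displacement_mm` once, at
#' the window midpoint.
#'
#' @param peak_displacement_mm Nonnegative peak skin displacement, in mm.
#' @param onset_s Nonnegative pulse onset time, in seconds.
#' @param duration_s Positive pulse duration, in seconds.
#' @param shape `"raised_cosine"` (smooth, continuous) or `"triangular"`.
#' @return An object of class `swallow_waveform`.
#' @examples
#' wf <- swallow_waveform(6, onset_s = 8, duration_s = 4)
#' waveform_displacement(wf, c(7, 10, 13))
#' @export
swallow_waveform <- function(peak_displacement_mm, onset_s, duration_s,
                             shape = c("raised_cosine", "triangular")) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(peak_displacement_mm), length(peak_displacement_mm) == 1,
            peak_displacement_mm >= 0,
            is.numeric(onset_s), onset_s >= 0,
            is.numeric(duration_s), duration_s > 0)
  structure(list(peak_displacement_mm = peak_displacement_mm,
                 onset_s = onset_s, duration_s = duration_s, shape = shape),
            class = "swallow_waveform")
}

#' Evaluate a swallow waveform
#'
#' @param wf A [swallow_waveform()].
#' @param t Numeric vector of times, in seconds.
#' @return Displacement in mm at each time, zero outside the pulse window.
#' @export
waveform_displacement <- function(wf, t) {
  stopifnot(inherits(wf, "swallow_waveform"))
  u <- (t - wf$onset_s) / wf$duration_s
  inside <- u >= 0 & u <= 1
  d <- numeric(length(t))
  if (wf$shape == "raised_cosine") {
    d[inside] <- wf$peak_displacement_mm / 2 * (1 - cos(2 * pi * u[inside]))
  } else {
    d[inside] <- wf$peak_displacement_mm * (1 - abs(2 * u[inside] - 1))
  }
  d
}

#' @export
print.swallow_waveform <- function(x, ...) {
  cat(sprintf("swallow waveform: %s, peak %.2f mm, window [%.1f, %.1f] s\n",
              x$shape, x$peak_displacement_mm, x$onset_s,
              x$onset_s + x$duration_s))
  invisible(x)
}

#' Guide-voice swallow schedule
#'
#' The recording protocol asks the subject to swallow three times, cued by a
#' pre-recorded voice, so swallow timing is constant across sessions. The
#' schedule holds the three cue onsets and the analysis window placed at each
#' cue. Defaults place swallows at 8, 18 and 28 s of a 36 s recording, each
#' lasting about 4 s, analyzed in a 6 s window starting at the cue.
#'
#' One schedule object is shared by the simulator and the analysis so the two
#' cannot drift apart.
#'
#' @param onset_s Three strictly increasing cue onsets, seconds.
#' @param swallow_s Nominal swallow duration used by the simulator, seconds.
#' @param window_s Width of the analysis window starting at each cue, seconds.
#' @return An object of class `guide_schedule`.
#' @export
guide_schedule <- function(onset_s = c(8, 18, 28), swallow_s = 4, window_s = 6) {
  stopifnot(length(onset_s) == 3, all(diff(onset_s) > 0),
            swallow_s > 0, window_s >= swallow_s)
  if (any(onset_s[-1] < onset_s[-3] + window_s))
    stop("guide schedule windows overlap")
  structure(list(onset_s = onset_s, swallow_s = swallow_s, window_s = window_s),
            class = "guide_schedule")
}

#' Three waveforms realizing a guide schedule with the given peaks
#'
#' @param schedule A [guide_schedule()].
#' @param peaks Three peak displacements, mm.
#' @param shape Waveform shape, see [swallow_waveform()].
#' @return List of three [swallow_waveform()]s at the schedule's cue onsets.
#' @export
schedule_waveforms <- function(schedule, peaks = c(6, 6, 6),
                               shape = "raised_cosine") {
  stopifnot(length(peaks) == 3)
  lapply(1:3, function(k)
    swallow_waveform(peaks[k], schedule$onset_s[k], schedule$swallow_s, shape))
}
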