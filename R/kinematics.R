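#' Pixel-to-millimeter calibration from the known sticker diameter
#'
#' The stickers have a known physical diameter (5 mm in the protocol), so
#' the scale of the image is the ratio of that diameter to the diameter
#' observed in pixels on the first frame. The mean over all first-frame
#' recognized markers is used.
#'
#' @param tracks A `marker_tracks` object.
#' @param marker_diameter_mm Known sticker diameter, mm.
#' @return An object of class `calibration_scale` with fields `mm_per_px`,
#'   `source_diameter_mm`, `source_diameter_px`.
#' @examples
#' # a 5 mm sticker spanning 50 px gives 0.1 mm/px
#' @export
estimate_scale <- function(tracks, marker_diameter_mm = 5) {
  stopifnot(marker_diameter_mm > 0)
  f1 <- tracks[tracks$frame == 1 & tracks$recognized, ]
  d <- f1$diameter_px[is.finite(f1$diameter_px) & f1$diameter_px > 0]
  if (length(d) == 0)
    stop("no marker with a positive diameter recognized in the first frame")
  dpx <- mean(d)
  structure(list(mm_per_px = marker_diameter_mm / dpx,
                 source_diameter_mm = marker_diameter_mm,
                 source_diameter_px = dpx),
            class = "calibration_scale")
}

#' @export
print.calibration_scale <- function(x, ...) {
  cat(sprintf("calibration: %.3f mm / %.2f px = %.5f mm/px\n",
              x$source_diameter_mm, x$source_diameter_px, x$mm_per_px))
  invisible(x)
}

#' Dropout-robust mean vertical trajectory
#'
#' Per frame, the average y over the markers recognized in that frame;
#' unrecognized markers are simply excluded. Because the nine markers sit at
#' different heights, each marker's y enters the average as its displacement
#' from that marker's own reference level (its median recognized y), plus
#' the common mean reference — when every marker is visible this equals the
#' plain arithmetic mean, and when the recognized subset changes the
#' trajectory does not jump by the missing marker's height offset. Frames
#' where no marker is recognized become gaps, filled by linear interpolation
#' between the nearest valid frames (held constant at the ends).
#'
#' @param tracks A `marker_tracks` object.
#' @return Numeric vector of per-frame mean y (px) with attributes
#'   `gap_fraction` (fraction of fully-gapped frames) and `gaps` (their
#'   indices).
#' @export
mean_trajectory <- function(tracks) {
  nf <- attr(tracks, "n_frames") %||% max(tracks$frame)
  y <- rep(NA_real_, nf)
  ok <- tracks$recognized & is.finite(tracks$y_px)
  ref <- tapply(tracks$y_px[ok], tracks$label[ok], stats::median)
  disp <- tracks$y_px[ok] - ref[tracks$label[ok]]
  means <- tapply(disp, tracks$frame[ok], mean) + mean(ref)
  y[as.integer(names(means))] <- means
  gaps <- which(is.na(y))
  if (length(gaps) == nf) stop("no marker recognized in any frame")
  if (length(gaps) > 0) {
    good <- which(!is.na(y))
    y[gaps] <- if (length(good) == 1) y[good]
               else stats::approx(good, y[good], xout = gaps, rule = 2)$y
  }
  attr(y, "gap_fraction") <- length(gaps) / nf
  attr(y, "gaps") <- gaps
  y
}

#' Locate the three swallows
#'
#' In schedule mode (default) the three analysis windows are placed from the
#' guide-voice cue times; because subjects swallow on cue, this is the
#' protocol's native segmentation. In auto mode the three largest-amplitude
#' displacement pulses of the mean trajectory are found instead and widened
#' to `half_width_s` on each side.
#'
#' @param n_frames Number of frames in the session.
#' @param fps Frame rate.
#' @param schedule A [guide_schedule()] (schedule mode).
#' @param mode `"schedule"` or `"auto"`.
#' @param trajectory Mean y trajectory (required in auto mode).
#' @param half_width_s Half-width of auto windows, seconds.
#' @return List of three `swallow_segment` objects, each with `index` and
#'   half-open `frame_range` `[start, end)` (1-based).
#' @examples
#' seg <- segment_swallows(1080, 30)
#' sapply(seg, function(s) s$frame_range)
#' @export
segment_swallows <- function(n_frames, fps, schedule = guide_schedule(),
                             mode = c("schedule", "auto"),
                             trajectory = NULL, half_width_s = 3) {
  mode <- match.arg(mode)
  stopifnot(n_frames >= 3, fps > 0)
  if (mode == "schedule") {
    rng <- lapply(1:3, function(k) {
      s <- round(schedule$onset_s[k] * fps)
      e <- round((schedule$onset_s[k] + schedule$window_s) * fps)
      c(max(1, s), min(n_frames + 1, e))
    })
  } else {
    if (is.null(trajectory)) stop("auto mode needs the mean trajectory")
    d <- abs(trajectory - stats::median(trajectory))
    if (max(d) <= .Machine$double.eps^0.5)
      stop("flat trajectory: no swallow pulses found; use schedule mode")
    pk <- pracma::findpeaks(as.numeric(d), minpeakheight = 0.2 * max(d),
                            minpeakdistance = max(1, round(half_width_s * fps)),
                            sortstr = TRUE)
    if (is.null(pk) || nrow(pk) < 3)
      stop("auto segmentation found fewer than 3 pulses; use schedule mode")
    centers <- sort(pk[1:3, 2])
    hw <- round(half_width_s * fps)
    rng <- lapply(1:3, function(k)
      c(max(1, centers[k] - hw), min(n_frames + 1, centers[k] + hw)))
    # trim overlaps at the midpoint between adjacent pulses
    for (k in 1:2) if (rng[[k]][2] > rng[[k + 1]][1]) {
      mid <- floor((centers[k] + centers[k + 1]) / 2)
      rng[[k]][2] <- mid; rng[[k + 1]][1] <- mid
    }
  }
  lapply(1:3, function(k) {
    stopifnot(rng[[k]][2] > rng[[k]][1])
    structure(list(index = k, frame_range = rng[[k]]),
              class = "swallow_segment")
  })
}

#' Excursion of the mean trajectory during one swallow
#'
#' The excursion ("marker distance") is the range — maximum minus minimum —
#' of the mean vertical trajectory within the swallow window, converted to
#' millimeters. Because it is a range, the direction of the image y-axis
#' never affects it.
#'
#' @param mean_y Per-frame mean y trajectory, px.
#' @param segment A `swallow_segment`.
#' @param scale A `calibration_scale` (or a bare mm-per-px number).
#' @return Nonnegative excursion in mm.
#' @export
swallow_excursion <- function(mean_y, segment, scale) {
  mm_per_px <- if (inherits(scale, "calibration_scale")) scale$mm_per_px
               else as.numeric(scale)
  r <- segment$frame_range
  idx <- seq.int(r[1], r[2] - 1)
  if (length(idx) == 0 || r[1] < 1 || r[2] - 1 > length(mean_y))
    stop("segment lies outside the trajectory")
  (max(mean_y[idx]) - min(mean_y[idx])) * mm_per_px
}

#' Session distance: the median over the three swallows
#'
#' The median, not the mean, summarizes the three per-swallow excursions, so
#' that a single corrupt swallow (markers moving much more or less than
#' usual) does not distort the session value.
#'
#' @param excursions Exactly three per-swallow excursions, mm.
#' @return Their median, mm.
#' @export
session_distance <- function(excursions) {
  if (length(excursions) != 3)
    stop("a session has exactly three swallows")
  stats::median(excursions)
}

#' Full per-session kinematic analysis
#'
#' Chains calibration, mean trajectory, swallow segmentation and excursion
#' into the one scalar the trial compares: the session distance in mm.
#'
#' Two excursion orders are available. The default averages the recognized
#' marker y-coordinates per frame and takes the range of that mean
#' trajectory (consistent with how dropout is handled); the alternative
#' takes each marker's own range and averages those.
#'
#' @param tracks A `marker_tracks` object.
#' @param marker_diameter_mm Known sticker diameter, mm.
#' @param fps Frame rate (defaults to the tracks attribute).
#' @param schedule A [guide_schedule()].
#' @param mode Segmentation mode, `"schedule"` or `"auto"`.
#' @param excursion_method `"mean_then_excursion"` (default) or
#'   `"per_marker_then_mean"`.
#' @param subject,timepoint Optional identifiers carried into the result.
#' @return An object of class `session_distance` with fields `subject`,
#'   `timepoint`, `scale_mm_per_px`, `excursions_mm`, `distance_mm`,
#'   `gap_fraction`.
#' @export
analyze_session <- function(tracks, marker_diameter_mm = 5, fps = NULL,
                            schedule = guide_schedule(),
                            mode = c("schedule", "auto"),
                            excursion_method = c("mean_then_excursion",
                                                 "per_marker_then_mean"),
                            subject = NA_character_,
                            timepoint = NA_character_) {
  mode <- match.arg(mode)
  excursion_method <- match.arg(excursion_method)
  fps <- fps %||% attr(tracks, "fps")
  if (is.null(fps) || !is.finite(fps)) stop("frame rate unknown")
  nf <- attr(tracks, "n_frames") %||% max(tracks$frame)
  scale <- estimate_scale(tracks, marker_diameter_mm)
  my <- mean_trajectory(tracks)
  segs <- segment_swallows(nf, fps, schedule, mode, trajectory = my)
  exc <- if (excursion_method == "mean_then_excursion") {
    vapply(segs, function(s) swallow_excursion(my, s, scale), numeric(1))
  } else {
    vapply(segs, function(s) per_marker_excursion(tracks, s, scale),
           numeric(1))
  }
  structure(list(subject = subject, timepoint = timepoint,
                 scale_mm_per_px = scale$mm_per_px,
                 excursions_mm = exc,
                 distance_mm = session_distance(exc),
                 gap_fraction = attr(my, "gap_fraction")),
            class = "session_distance")
}

# Alternative order: each marker's own range within the window (computed on
# its recognized frames only), averaged over markers seen in the window.
per_marker_excursion <- function(tracks, segment, scale) {
  r <- segment$frame_range
  sub <- tracks[tracks$frame >= r[1] & tracks$frame < r[2] &
                  tracks$recognized, ]
  if (nrow(sub) == 0) stop("no recognized marker inside a swallow window")
  rng <- tapply(sub$y_px, sub$label, function(y) max(y) - min(y))
  mean(rng, na.rm = TRUE) * scale$mm_per_px
}

#' @export
print.session_distance <- function(x, ...) {
  cat(sprintf("session distance: %.3f mm (subject %s, timepoint %s)\n",
              x$distance_mm, x$subject, x$timepoint))
  cat(sprintf("  swallow excursions: %s mm; scale %.4f mm/px; gaps %.1f%%\n",
              paste(sprintf("%.3f", x$excursions_mm), collapse = ", "),
              x$scale_mm_per_px, 100 * x$gap_fraction))
  invisible(x)
}

#' Write a session analysis to JSON
#'
#' @param x A `session_distance` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_session_distance <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
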