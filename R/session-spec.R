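MARKER_LABELS <- c("H1", "H2", "H3", "M1", "M2", "M3", "L1", "L2", "L3")
MARKER_COLORS <- c("blue", "orange", "green", "yellow")

# Reference RGB (0..1) used to paint each sticker color. Chosen to sit near
# the middle of the corresponding default hue band, strongly saturated.
marker_rgb <- function(color) {
  switch(color,
         blue   = c(0.10, 0.25, 0.90),
         orange = c(0.95, 0.55, 0.08),
         green  = c(0.10, 0.80, 0.20),
         yellow = c(0.95, 0.85, 0.10),
         stop("unknown marker color: ", color))
}

#' Default 3x3 sticker layout, in mm relative to the grid center
#'
#' Three stickers sit 1 cm above the incision line (row H), three on the line
#' (row M) and three 1 cm below it (row L). The incision is horizontal, so
#' rows are separated by `row_gap_mm` vertically; lateral spacing is not
#' prescribed by the protocol and defaults to 15 mm. Coordinates follow the
#' image convention: y increases downward, so row H has the most negative y.
#'
#' @param col_gap_mm Lateral center-to-center spacing, mm.
#' @param row_gap_mm Vertical spacing between adjacent rows, mm.
#' @return A 9x2 matrix (columns `x_mm`, `y_mm`) with rownames H1..L3.
#' @export
default_grid_centers <- function(col_gap_mm = 15, row_gap_mm = 10) {
  g <- expand.grid(col = -1:1, row = -1:1)
  m <- cbind(x_mm = g$col * col_gap_mm, y_mm = g$row * row_gap_mm)
  rownames(m) <- MARKER_LABELS
  m
}

# Fixed repeating color assignment: the four sticker colors cycle over the
# nine grid positions in reading order.
default_color_assignment <- function() {
  stats::setNames(rep(MARKER_COLORS, length.out = 9), MARKER_LABELS)
}

#' Specification of one synthetic recording session
#'
#' Describes everything needed to render a front-view neck recording of the
#' guided three-swallow protocol: the camera geometry (image size and
#' mm-per-pixel scale), the nine colored stickers, the three swallow
#' waveforms, and the nuisance processes (pixel noise, illumination drift,
#' marker dropout). Given a seed the rendered session is fully deterministic.
#'
#' `row_gain` scales the swallow displacement per sticker row; values below 1
#' emulate skin tethered by post-surgical adhesion, the phenotype the
#' measurement system is built to detect.
#'
#' @param image_size_px Width and height of each frame, pixels.
#' @param scale_mm_per_px True physical scale of the image, mm per pixel.
#' @param marker_diameter_mm True sticker diameter (the protocol uses 5 mm).
#' @param grid_centers_mm 9x2 matrix of sticker centers, mm relative to the
#'   grid center (rownames H1..L3); see [default_grid_centers()].
#' @param color_assignment Named character vector mapping each of the nine
#'   labels to one of `"blue"`, `"orange"`, `"green"`, `"yellow"`.
#' @param schedule A [guide_schedule()].
#' @param waveforms List of exactly three [swallow_waveform()]s with
#'   non-overlapping windows; default realizes `schedule` with 6 mm peaks.
#' @param row_gain Named multipliers in \[0,1\] for rows `H`, `M`, `L`.
#' @param fps Frame rate, frames per second.
#' @param duration_s Recording length, seconds.
#' @param dropout_prob Per-marker per-frame probability that the sticker is
#'   not visible (occlusion/washout).
#' @param illumination_drift Amplitude of a slow sinusoidal brightness
#'   modulation (fraction of nominal brightness).
#' @param noise_sd Standard deviation of additive luminance pixel noise
#'   (intensity units, image scale 0..1).
#' @param x_jitter_mm Amplitude of small lateral marker jitter, mm (off by
#'   default; front-view swallowing moves markers along y only).
#' @param place_jitter_mm SD of the random, time-constant placement offset
#'   of each sticker from its nominal grid position, mm. Stickers are
#'   attached by hand, so exact grid placement would be unrealistic.
#' @param seed Integer RNG seed.
#' @return An object of class `session_spec`.
#' @examples
#' spec <- session_spec(duration_s = 12, fps = 10,
#'                      schedule = guide_schedule(c(2, 5.5, 9), 2, 3))
#' @export
session_spec <- function(image_size_px = c(480, 360),
                         scale_mm_per_px = 0.25,
                         marker_diameter_mm = 5,
                         grid_centers_mm = default_grid_centers(),
                         color_assignment = default_color_assignment(),
                         schedule = guide_schedule(),
                         waveforms = schedule_waveforms(schedule),
                         row_gain = c(H = 1, M = 1, L = 1),
                         fps = 30,
                         duration_s = 36,
                         dropout_prob = 0,
                         illumination_drift = 0,
                         noise_sd = 0.01,
                         x_jitter_mm = 0,
                         place_jitter_mm = 1,
                         seed = 1L) {
  stopifnot(length(image_size_px) == 2, all(image_size_px >= 32),
            scale_mm_per_px > 0, marker_diameter_mm > 0,
            fps > 0, duration_s > 0,
            length(dropout_prob) %in% c(1L, 9L),
            all(dropout_prob >= 0), all(dropout_prob <= 1),
            illumination_drift >= 0, illumination_drift < 1,
            noise_sd >= 0, x_jitter_mm >= 0, place_jitter_mm >= 0)
  if (!identical(sort(rownames(grid_centers_mm)), sort(MARKER_LABELS)))
    stop("grid_centers_mm must have rownames H1,H2,H3,M1,M2,M3,L1,L2,L3")
  if (!identical(sort(names(color_assignment)), sort(MARKER_LABELS)))
    stop("color_assignment must name all nine markers")
  if (!all(color_assignment %in% MARKER_COLORS))
    stop("marker colors must be drawn from: ",
         paste(MARKER_COLORS, collapse = ", "))
  if (length(waveforms) != 3 || !all(vapply(waveforms, inherits, TRUE,
                                            "swallow_waveform")))
    stop("waveforms must be a list of three swallow_waveform objects")
  win <- t(vapply(waveforms, function(w)
    c(w$onset_s, w$onset_s + w$duration_s), numeric(2)))
  win <- win[order(win[, 1]), , drop = FALSE]
  if (any(win[-1, 1] < win[-3, 2]))
    stop("swallow windows overlap; the three pulses must be disjoint in time")
  if (max(win[, 2]) > duration_s)
    stop("a swallow window extends past the end of the recording")
  if (!identical(sort(names(row_gain)), c("H", "L", "M")) ||
      any(row_gain < 0) || any(row_gain > 1))
    stop("row_gain must be named H, M, L with values in [0, 1]")
  structure(list(image_size_px = as.numeric(image_size_px),
                 scale_mm_per_px = scale_mm_per_px,
                 marker_diameter_mm = marker_diameter_mm,
                 grid_centers_mm = grid_centers_mm[MARKER_LABELS, , drop = FALSE],
                 color_assignment = color_assignment[MARKER_LABELS],
                 schedule = schedule,
                 waveforms = waveforms,
                 row_gain = row_gain[c("H", "M", "L")],
                 fps = fps, duration_s = duration_s,
                 dropout_prob = {
                   if (length(dropout_prob) == 9 && !is.null(names(dropout_prob)))
                     dropout_prob <- dropout_prob[MARKER_LABELS]
                   dropout_prob
                 },
                 illumination_drift = illumination_drift,
                 noise_sd = noise_sd, x_jitter_mm = x_jitter_mm,
                 place_jitter_mm = place_jitter_mm,
                 seed = as.integer(seed)),
            class = "session_spec")
}

#' @export
print.session_spec <- function(x, ...) {
  cat(sprintf(paste0("session spec: %dx%d px @ %.3g mm/px, %g fps x %g s, ",
                     "9 markers (d=%g mm)\n"),
              x$image_size_px[1], x$image_size_px[2], x$scale_mm_per_px,
              x$fps, x$duration_s, x$marker_diameter_mm))
  cat(sprintf("  dropout %.2g, illumination drift %.2g, noise sd %.2g, seed %d\n",
              x$dropout_prob, x$illumination_drift, x$noise_sd, x$seed))
  invisible(x)
}
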