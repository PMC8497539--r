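#' Generate a synthetic swallow session with ground truth
#'
#' Simulates one front-view recording of the guided three-swallow protocol:
#' nine anti-aliased colored disks on a textured skin-tone background, moving
#' vertically according to the session's swallow waveforms, with optional
#' pixel noise, slow illumination drift and random marker dropout. Frames are
#' rendered lazily and deterministically (per-frame seeds are fixed at
#' generation time), so an arbitrarily long session costs one frame of
#' memory.
#'
#' Ground truth includes per-frame true centroids, the per-frame visibility
#' mask, the true excursion of the mean marker trajectory within each guide
#' window, and the session distance (their median).
#'
#' @param spec A [session_spec()].
#' @return An object of class `swallow_session` with elements `spec`, `truth`
#'   (`x_px`, `y_px` frames x 9 matrices, `recognized` mask, `t_s`,
#'   `excursion_mm`, `session_distance_mm`) and `n_frames`. Frames are
#'   obtained with [session_frame()] or written with [write_session()].
#' @examples
#' spec <- session_spec(duration_s = 12, fps = 5,
#'                      schedule = guide_schedule(c(2, 5.5, 9), 2, 3))
#' ses <- generate_session(spec)
#' ses$truth$session_distance_mm
#' @export
generate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  n <- round(spec$fps * spec$duration_s)
  t_s <- (seq_len(n) - 1) / spec$fps
  w <- spec$image_size_px[1]; h <- spec$image_size_px[2]

  draws <- with_seed(spec$seed, {
    fseeds <- sample.int(.Machine$integer.max - 1L, n)
    p <- rep(spec$dropout_prob, length.out = 9)
    rec <- matrix(stats::runif(n * 9) >= rep(p, each = n), n, 9,
                  dimnames = list(NULL, MARKER_LABELS))
    phases <- stats::runif(9, 0, 2 * pi)
    place <- matrix(stats::rnorm(18, 0, spec$place_jitter_mm), 9, 2)
    list(fseeds = fseeds, rec = rec, phases = phases, place = place)
  })

  # True vertical displacement (mm, positive = upward skin motion) shared by
  # all markers before the row gain is applied.
  base_d <- rowSums(vapply(spec$waveforms, waveform_displacement,
                           numeric(n), t = t_s))
  row_of <- substr(MARKER_LABELS, 1, 1)
  gain <- spec$row_gain[row_of]

  # nominal grid plus the hand-placement scatter of each sticker
  cx0 <- (w + 1) / 2 + (spec$grid_centers_mm[, "x_mm"] +
                          draws$place[, 1]) / spec$scale_mm_per_px
  cy0 <- (h + 1) / 2 + (spec$grid_centers_mm[, "y_mm"] +
                          draws$place[, 2]) / spec$scale_mm_per_px
  # y grows downward; upward displacement decreases y.
  y_px <- outer(rep(1, n), cy0) - outer(base_d, gain) / spec$scale_mm_per_px
  x_px <- outer(rep(1, n), cx0)
  if (spec$x_jitter_mm > 0) {
    jit <- spec$x_jitter_mm *
      sin(outer(2 * pi * t_s / spec$duration_s * 3, rep(1, 9)) +
            outer(rep(1, n), draws$phases))
    x_px <- x_px + jit / spec$scale_mm_per_px
  }
  colnames(y_px) <- colnames(x_px) <- MARKER_LABELS

  # Excursion of the true mean trajectory inside each guide window.
  mean_d <- base_d * mean(gain)
  exc <- vapply(1:3, function(k) {
    on <- spec$schedule$onset_s[k]
    idx <- t_s >= on & t_s < on + spec$schedule$window_s
    if (!any(idx)) return(NA_real_)
    max(mean_d[idx]) - min(mean_d[idx])
  }, numeric(1))

  truth <- list(x_px = x_px, y_px = y_px, recognized = draws$rec, t_s = t_s,
                excursion_mm = exc,
                session_distance_mm = stats::median(exc))
  structure(list(spec = spec, truth = truth, n_frames = n,
                 frame_seeds = draws$fseeds,
                 background = session_background(w, h)),
            class = "swallow_session")
}

# Static skin-tone background: vertical brightness gradient plus a faint 2-D
# sinusoidal texture. Saturation stays below the marker thresholds.
session_background <- function(w, h) {
  base <- c(0.82, 0.66, 0.58)
  grad <- 1 + 0.08 * (seq_len(h) / h - 0.5)
  tex <- 0.015 * outer(sin(2 * pi * seq_len(h) / 53),
                       sin(2 * pi * seq_len(w) / 37))
  plane <- grad * matrix(1, h, w) + tex
  array(rep(as.vector(plane), 3) * rep(base, each = h * w), c(h, w, 3))
}

#' Render one frame of a synthetic session
#'
#' @param session A [generate_session()] result.
#' @param f Frame index (1-based).
#' @return An `height x width x 3` RGB array in \[0,1\], identical across
#'   repeated calls.
#' @export
session_frame <- function(session, f) {
  stopifnot(inherits(session, "swallow_session"),
            f >= 1, f <= session$n_frames)
  spec <- session$spec
  w <- spec$image_size_px[1]; h <- spec$image_size_px[2]
  img <- session$background
  if (spec$noise_sd > 0) {
    noise <- with_seed(session$frame_seeds[f],
                       stats::rnorm(h * w, 0, spec$noise_sd))
    img <- img + rep(noise, 3)
  }
  r <- spec$marker_diameter_mm / 2 / spec$scale_mm_per_px
  for (m in seq_len(9)) {
    if (!session$truth$recognized[f, m]) next
    cx <- session$truth$x_px[f, m]; cy <- session$truth$y_px[f, m]
    xs <- max(1, floor(cx - r - 2)):min(w, ceiling(cx + r + 2))
    ys <- max(1, floor(cy - r - 2)):min(h, ceiling(cy + r + 2))
    dist <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
    alpha <- clamp(r + 0.5 - dist)   # pixel-coverage anti-aliasing
    col <- marker_rgb(spec$color_assignment[[m]])
    for (ch in 1:3)
      img[ys, xs, ch] <- (1 - alpha) * img[ys, xs, ch] + alpha * col[ch]
  }
  if (spec$illumination_drift > 0) {
    t_f <- (f - 1) / spec$fps
    img <- img * (1 + spec$illumination_drift *
                    sin(2 * pi * t_f / spec$duration_s))
  }
  clamp(img)
}

#' @export
print.swallow_session <- function(x, ...) {
  cat(sprintf("synthetic swallow session: %d frames @ %g fps (%g s)\n",
              x$n_frames, x$spec$fps, x$spec$duration_s))
  cat(sprintf("  true excursions: %s mm; session distance %.3f mm\n",
              paste(sprintf("%.3f", x$truth$excursion_mm), collapse = ", "),
              x$truth$session_distance_mm))
  cat(sprintf("  marker visibility: %.1f%% of frame-markers\n",
              100 * mean(x$truth$recognized)))
  invisible(x)
}

#' Write a session to disk as numbered PNG frames plus metadata
#'
#' Writes `frame_000001.png` ... to `dir`, a `manifest.json` (fps, marker
#' diameter, labels, frame count, optional subject/timepoint), the ground
#' truth as `truth.csv` (frame, label, x_px, y_px, recognized) and a
#' `truth_summary.json` with the per-swallow excursions and session distance.
#'
#' @param session A `swallow_session`.
#' @param dir Output directory (created if missing).
#' @param subject,timepoint Optional identifiers stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, subject = NULL, timepoint = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_len(session$n_frames)) {
    png::writePNG(session_frame(session, f),
                  file.path(dir, sprintf("frame_%06d.png", f)))
  }
  manifest <- list(fps = session$spec$fps,
                   marker_diameter_mm = session$spec$marker_diameter_mm,
                   labels = MARKER_LABELS,
                   n_frames = session$n_frames,
                   subject = subject, timepoint = timepoint)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  tr <- session$truth
  gt <- data.frame(frame = rep(seq_len(session$n_frames), 9),
                   label = rep(MARKER_LABELS, each = session$n_frames),
                   x_px = as.vector(tr$x_px), y_px = as.vector(tr$y_px),
                   recognized = as.vector(tr$recognized))
  utils::write.csv(gt, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(list(excursion_mm = tr$excursion_mm,
                            session_distance_mm = tr$session_distance_mm),
                       file.path(dir, "truth_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
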