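#' Track the nine markers through a frame sequence
#'
#' Runs the full detection chain: the region of interest is fixed on the
#' first frame ([init_roi()]), then every frame is color-segmented
#' ([segment_colors()]) and its blobs labeled on the grid ([assign_grid()]),
#' matching against the previous frame's positions when markers are missing.
#' A label whose new centroid would jump more than `max_jump_px` from its
#' last recognized position is rejected for that frame — this suppresses the
#' momentary top/bottom marker swaps and illumination flicker seen during
#' fast swallows.
#'
#' @param frames Anything accepted by [frame_source()]: a synthetic session,
#'   a frame directory, or a list of RGB arrays.
#' @param roi Optional first-frame rectangle `c(xmin, ymin, xmax, ymax)`.
#' @param colors List of [color_spec()]s.
#' @param min_area_px Minimum blob area, pixels.
#' @param max_jump_px Per-frame displacement gate; default 3x the median
#'   first-frame marker diameter.
#' @param fps Frame-rate override recorded in the result.
#' @return An object of class `marker_tracks`: a long data.frame with
#'   columns `frame`, `label`, `recognized`, `x_px`, `y_px`,
#'   `diameter_px`, and attributes `n_frames`, `fps`, `roi`.
#' @export
track_markers <- function(frames, roi = NULL, colors = default_color_specs(),
                          min_area_px = 20, max_jump_px = NULL,
                          fps = NULL) {
  fs <- frame_source(frames)
  if (fs$n_frames < 2) stop("at least two frames are required")
  first <- fs$get(1)
  box <- init_roi(first, roi, colors, min_area_px)

  per_frame <- vector("list", fs$n_frames)
  blobs1 <- segment_colors(first, box, colors, min_area_px)
  ref <- roi_grid_template(box)
  a1 <- assign_grid(blobs1, reference = ref)
  per_frame[[1]] <- a1
  if (is.null(max_jump_px)) {
    d1 <- stats::median(a1$equiv_diameter_px, na.rm = TRUE)
    max_jump_px <- if (is.finite(d1)) 3 * d1 else Inf
  }
  last_seen <- ref
  last_seen[a1$recognized, 1] <- a1$x_px[a1$recognized]
  last_seen[a1$recognized, 2] <- a1$y_px[a1$recognized]

  for (f in 2:fs$n_frames) {
    blobs <- segment_colors(fs$get(f), box, colors, min_area_px)
    a <- assign_grid(blobs, reference = last_seen)
    # displacement gate against the last recognized position of each label
    jump <- sqrt((a$x_px - last_seen[, 1])^2 + (a$y_px - last_seen[, 2])^2)
    bad <- a$recognized & !is.na(jump) & jump > max_jump_px
    a$recognized[bad] <- FALSE
    a$x_px[bad] <- NA_real_; a$y_px[bad] <- NA_real_
    a$equiv_diameter_px[bad] <- NA_real_
    ok <- a$recognized
    last_seen[ok, 1] <- a$x_px[ok]
    last_seen[ok, 2] <- a$y_px[ok]
    per_frame[[f]] <- a
  }

  out <- do.call(rbind, per_frame)
  out <- data.frame(frame = rep(seq_len(fs$n_frames), each = 9), out,
                    row.names = NULL)
  names(out)[names(out) == "equiv_diameter_px"] <- "diameter_px"
  structure(out, class = c("marker_tracks", "data.frame"),
            n_frames = fs$n_frames, fps = fps %||% fs$fps, roi = box)
}

# Expected 3x3 grid inside a region of interest, used as the matching
# template when the first frame itself has missing markers.
roi_grid_template <- function(box) {
  xs <- box[1] + (box[3] - box[1]) * c(0.25, 0.5, 0.75)
  ys <- box[2] + (box[4] - box[2]) * c(0.25, 0.5, 0.75)
  m <- cbind(x = rep(xs, 3), y = rep(ys, each = 3))
  rownames(m) <- MARKER_LABELS
  m
}

#' @export
print.marker_tracks <- function(x, ...) {
  nf <- attr(x, "n_frames")
  rec <- tapply(x$recognized, x$label, mean)[MARKER_LABELS]
  cat(sprintf("marker tracks: %d frames, fps %s\n", nf,
              format(attr(x, "fps"))))
  cat("  recognized fraction per label:\n")
  print(round(rec, 3))
  invisible(x)
}

#' Write / read tracks in the interchange CSV dialect
#'
#' Columns: frame, label, recognized, x_px, y_px, diameter_px.
#'
#' @param tracks A `marker_tracks` object.
#' @param path CSV file path.
#' @param fps Frame rate to attach on read (if known).
#' @return `write_tracks` returns `path` invisibly; `read_tracks` a
#'   `marker_tracks` object.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path, fps = NA_real_) {
  df <- utils::read.csv(path)
  need <- c("frame", "label", "recognized", "x_px", "y_px", "diameter_px")
  if (!all(need %in% names(df)))
    stop("tracks CSV must have columns: ", paste(need, collapse = ", "))
  df$recognized <- as.logical(df$recognized)
  structure(df, class = c("marker_tracks", "data.frame"),
            n_frames = max(df$frame), fps = fps, roi = NULL)
}
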