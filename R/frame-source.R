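#' Uniform access to a sequence of video frames
#'
#' Analysis functions accept either an in-memory synthetic session (frames
#' rendered on demand), a directory of numbered PNG/JPEG frames with an
#' optional `manifest.json`, or a plain list of RGB arrays. `frame_source()`
#' normalizes these to one interface.
#'
#' @param x A `swallow_session`, a directory path, or a list of
#'   `height x width x 3` arrays.
#' @param fps Frame rate override (required for a bare list without one).
#' @param ... Unused.
#' @return An object of class `frame_source` with `$n_frames`, `$fps`,
#'   `$get(i)` returning frame `i`, and `$manifest`.
#' @export
frame_source <- function(x, ...) UseMethod("frame_source")

#' @export
frame_source.frame_source <- function(x, ...) x

#' @rdname frame_source
#' @export
frame_source.swallow_session <- function(x, ...) {
  structure(list(n_frames = x$n_frames, fps = x$spec$fps,
                 get = function(i) session_frame(x, i),
                 manifest = list(fps = x$spec$fps,
                                 marker_diameter_mm = x$spec$marker_diameter_mm)),
            class = "frame_source")
}

#' @rdname frame_source
#' @export
frame_source.character <- function(x, ...) {
  stopifnot(length(x) == 1, dir.exists(x))
  files <- sort(list.files(x, pattern = "\\.(png|PNG|jpe?g|JPE?G)$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no image frames found in ", x)
  mf <- file.path(x, "manifest.json")
  manifest <- if (file.exists(mf)) jsonlite::read_json(mf, simplifyVector = TRUE)
              else list()
  structure(list(n_frames = length(files),
                 fps = manifest$fps %||% NA_real_,
                 get = function(i) read_frame(files[i]),
                 manifest = manifest),
            class = "frame_source")
}

#' @rdname frame_source
#' @export
frame_source.list <- function(x, fps = NA_real_, ...) {
  stopifnot(length(x) >= 1, all(vapply(x, function(f)
    is.array(f) && length(dim(f)) == 3 && dim(f)[3] == 3, TRUE)))
  structure(list(n_frames = length(x), fps = fps,
                 get = function(i) x[[i]], manifest = list(fps = fps)),
            class = "frame_source")
}

# Read a single frame; PNG through the png package, anything else through
# EBImage. Always returns an h x w x 3 array in [0,1].
read_frame <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    a <- EBImage::imageData(EBImage::readImage(path))
    aperm(a, c(2, 1, 3))  # EBImage stores x-major
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}
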