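#' Segment colored marker blobs in one frame
#'
#' Thresholds the frame in HSV space once per color spec, labels connected
#' components within the region of interest, and returns every component at
#' least `min_area_px` pixels large with its unweighted centroid and
#' equivalent-circle diameter.
#'
#' Coordinate convention: pixel centers at integer coordinates, origin at the
#' top-left, x rightward (column index) and y downward (row index), 1-based.
#'
#' @param frame `h x w x 3` RGB array in \[0,1\].
#' @param roi Region of interest `c(xmin, ymin, xmax, ymax)` in pixels, or
#'   `NULL` for the whole frame.
#' @param colors List of [color_spec()]s; see [default_color_specs()].
#' @param min_area_px Minimum component area in pixels.
#' @return A data.frame with columns `color`, `x_px`, `y_px`, `area_px`,
#'   `equiv_diameter_px`; zero rows when nothing is found.
#' @export
segment_colors <- function(frame, roi = NULL, colors = default_color_specs(),
                           min_area_px = 20) {
  stopifnot(is.array(frame), length(dim(frame)) == 3, dim(frame)[3] == 3,
            length(colors) >= 1, min_area_px >= 1)
  h <- dim(frame)[1]; w <- dim(frame)[2]
  if (is.null(roi)) roi <- c(1, 1, w, h)
  roi <- clip_roi(roi, w, h)
  sub <- frame[roi[2]:roi[4], roi[1]:roi[3], , drop = FALSE]
  hs <- rgb_to_hsv(sub)
  hp <- hs[, , 1]; sp <- hs[, , 2]; vp <- hs[, , 3]

  out <- lapply(colors, function(cs) {
    mask <- hsv_mask(hp, sp, vp, cs)
    if (!any(mask)) return(NULL)
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area_px)
    if (length(keep) == 0) return(NULL)
    idx <- which(lab %in% keep)
    ij <- arrayInd(idx, dim(lab))
    comp <- lab[idx]
    data.frame(color = cs$name,
               x_px = tapply(ij[, 2], comp, mean) + roi[1] - 1,
               y_px = tapply(ij[, 1], comp, mean) + roi[2] - 1,
               area_px = as.numeric(sizes[keep]),  # tapply orders by sorted id

               row.names = NULL)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(color = character(), x_px = numeric(), y_px = numeric(),
                      area_px = numeric())
  out$equiv_diameter_px <- 2 * sqrt(out$area_px / pi)
  rownames(out) <- NULL
  out
}

# Clip a rectangle to image bounds; errors if empty or fully outside.
clip_roi <- function(roi, w, h) {
  stopifnot(length(roi) == 4)
  if (roi[3] <= roi[1] || roi[4] <= roi[2])
    stop("roi has zero or negative area")
  if (roi[1] > w || roi[3] < 1 || roi[2] > h || roi[4] < 1)
    stop("roi lies outside the image")
  c(max(1, floor(roi[1])), max(1, floor(roi[2])),
    min(w, ceiling(roi[3])), min(h, ceiling(roi[4])))
}

#' Establish the first-frame region of interest
#'
#' The protocol designates the markers' region on the first frame. When a
#' rectangle is supplied it is clipped to the image and returned; otherwise
#' the bounding box of all detected color blobs, dilated by `margin_px`, is
#' used.
#'
#' @param first_frame `h x w x 3` RGB array.
#' @param roi Optional rectangle `c(xmin, ymin, xmax, ymax)`.
#' @param colors,min_area_px Passed to [segment_colors()] in automatic mode.
#' @param margin_px Dilation of the automatic bounding box, pixels.
#' @return A clipped rectangle `c(xmin, ymin, xmax, ymax)`.
#' @export
init_roi <- function(first_frame, roi = NULL, colors = default_color_specs(),
                     min_area_px = 20, margin_px = 20) {
  h <- dim(first_frame)[1]; w <- dim(first_frame)[2]
  if (!is.null(roi)) return(clip_roi(roi, w, h))
  blobs <- segment_colors(first_frame, NULL, colors, min_area_px)
  if (nrow(blobs) == 0)
    stop("no colored blobs found; supply an roi explicitly")
  r <- blobs$equiv_diameter_px / 2
  clip_roi(c(min(blobs$x_px - r) - margin_px, min(blobs$y_px - r) - margin_px,
             max(blobs$x_px + r) + margin_px, max(blobs$y_px + r) + margin_px),
           w, h)
}
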