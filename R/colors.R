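#' HSV threshold specification for one sticker color
#'
#' Markers are segmented by thresholding in HSV space, which separates
#' chromatic identity (hue) from illumination (value), making the detection
#' tolerant to brightness changes. A spec keeps a wrap-aware hue band plus
#' minimum saturation and value; skin and shadow fall below the saturation
#' floor.
#'
#' @param name One of `"blue"`, `"orange"`, `"green"`, `"yellow"`.
#' @param hue_range Two hue bounds in degrees. `lo > hi` denotes a band that
#'   wraps through 360/0 (e.g. red-ish bands).
#' @param sat_min,val_min Minimum saturation and value in \[0,1\].
#' @return An object of class `color_spec`.
#' @export
color_spec <- function(name, hue_range, sat_min = 0.4, val_min = 0.3) {
  stopifnot(name %in% MARKER_COLORS, length(hue_range) == 2,
            all(hue_range >= 0), all(hue_range < 360),
            sat_min >= 0, sat_min <= 1, val_min >= 0, val_min <= 1)
  structure(list(name = name, hue_range = as.numeric(hue_range),
                 sat_min = sat_min, val_min = val_min),
            class = "color_spec")
}

#' Default threshold bands for the four sticker colors
#'
#' Pairwise-disjoint hue bands: orange 15-40, yellow 45-70, green 90-150,
#' blue 200-260 degrees, with value >= 0.3 throughout. The saturation floor
#' is per color: skin tones sit inside the orange hue band at saturation
#' around 0.3, so orange (and, less so, green) need a higher floor than blue
#' and yellow; the floors are set so that a marker-edge pixel mixed roughly
#' half-and-half with skin is the faintest accepted pixel, which keeps
#' measured blob diameters close to the physical sticker diameter.
#'
#' @return A named list of four [color_spec()]s.
#' @export
default_color_specs <- function() {
  list(blue   = color_spec("blue",   c(200, 260), sat_min = 0.40),
       orange = color_spec("orange", c(15, 40),   sat_min = 0.60),
       green  = color_spec("green",  c(90, 150),  sat_min = 0.45),
       yellow = color_spec("yellow", c(45, 70),   sat_min = 0.40))
}

#' Convert RGB to HSV (hue in degrees)
#'
#' Standard hexcone conversion. Accepts a length-3 vector, a 3-row or
#' 3-column matrix, or an `h x w x 3` image array; channels must lie in
#' \[0,1\].
#'
#' @param x RGB input.
#' @return Matching shape with columns/planes (h, s, v): h in \[0,360),
#'   s and v in \[0,1\]. Achromatic pixels get h = 0, s = 0.
#' @examples
#' rgb_to_hsv(c(1, 0, 0))   # 0, 1, 1
#' rgb_to_hsv(c(0, 1, 0))   # 120, 1, 1
#' @export
rgb_to_hsv <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    stopifnot(d[3] == 3)
    m <- matrix(x, ncol = 3)
    out <- rgb_to_hsv(t(m))
    return(array(t(out), d, dimnames = list(NULL, NULL, c("h", "s", "v"))))
  }
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3)
    x <- matrix(x, nrow = 3)
  } else if (nrow(x) != 3 && ncol(x) == 3) {
    x <- t(x)
  }
  if (any(x < 0) || any(x > 1) || anyNA(x))
    stop("RGB channels must lie in [0, 1]")
  hsv <- grDevices::rgb2hsv(x[1, ], x[2, ], x[3, ], maxColorValue = 1)
  hsv[1, ] <- (hsv[1, ] * 360) %% 360
  rownames(hsv) <- c("h", "s", "v")
  hsv
}

# Logical mask of pixels matching one color spec, given h/s/v planes.
hsv_mask <- function(h, s, v, cspec) {
  lo <- cspec$hue_range[1]; hi <- cspec$hue_range[2]
  in_hue <- if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
  in_hue & s >= cspec$sat_min & v >= cspec$val_min
}
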