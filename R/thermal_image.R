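#' Radiometric thermal image
#'
#' A per-pixel temperature grid in degrees C. Pixel origin is top-left,
#' x grows rightward, y downward, and pixel centres sit at integer
#' coordinates (0-based), matching the projection convention of
#' [project_point()]. Values are stored as a `height x width` matrix whose
#' `[i, j]` entry is the pixel at x = j - 1, y = i - 1.
#'
#' @param values numeric matrix (height x width) of temperatures, degrees C.
#' @param timestamp optional capture time, seconds.
#' @return An object of class `thermal_image`.
#' @export
thermal_image <- function(values, timestamp = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1 || ncol(values) < 1)
    stop("image must have positive dimensions")
  if (!all(is.finite(values)))
    stop("image values must be finite")
  structure(list(values = values, width = ncol(values),
                 height = nrow(values), timestamp = timestamp),
            class = "thermal_image")
}

#' @export
print.thermal_image <- function(x, ...) {
  cat(sprintf("Thermal image: %d x %d px, %.2f to %.2f degC\n",
              x$width, x$height, min(x$values), max(x$values)))
  invisible(x)
}

#' Sample an image at integer pixel coordinates
#'
#' Nearest-pixel lookup used by fusion; coordinates are 0-based with the
#' origin at the top-left pixel centre.
#'
#' @param image a [thermal_image()].
#' @param x,y pixel coordinates (numeric vectors; rounded half-up).
#' @return Temperatures, with NA where the pixel falls outside the image.
#' @keywords internal
image_sample_nearest <- function(image, x, y) {
  ix <- round_half_up(x)
  iy <- round_half_up(y)
  ok <- ix >= 0 & ix <= image$width - 1 & iy >= 0 & iy <= image$height - 1
  out <- rep(NA_real_, length(x))
  out[ok] <- image$values[cbind(iy[ok] + 1L, ix[ok] + 1L)]
  out
}

# deterministic half-up rounding (round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)
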