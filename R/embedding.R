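#' Raised-cosine window specification
#'
#' Soft circular aperture used to embed the orientation signal: full
#' strength (weight 1) out to the plateau radius `r`, half-cosine ramp to 0
#' over `[r, r + w]`. All lengths are in degrees of visual angle; the
#' window's center is given relative to the field center, x rightward and y
#' upward.
#'
#' @param center_x,center_y Window center in degrees relative to field
#'   center.
#' @param r Plateau radius in degrees, > 0.
#' @param w Cosine ramp width in degrees, >= 0 (`w = 0` gives a hard-edged
#'   disk).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(center_x = 0, center_y = 0, r = 1.75, w = 0.875) {
  if (!is.numeric(r) || r <= 0) stop("`r` must be > 0 (degrees)", call. = FALSE)
  if (!is.numeric(w) || w < 0) stop("`w` must be >= 0 (degrees)", call. = FALSE)
  structure(list(center_x = center_x, center_y = center_y, r = r, w = w),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec center (%g, %g) deg, r = %g deg, w = %g deg>\n",
              x$center_x, x$center_y, x$r, x$w))
  invisible(x)
}

# Distance map (degrees) from the window center for a height x width field.
# Centers are evaluated at real-valued positions: no rounding to the pixel
# grid, so sub-pixel placement is exact. Row 1 is the top of the image and
# y increases upward in degrees.
window_distance_map <- function(height, width, spec, ppd) {
  cx <- (width + 1) / 2 + spec$center_x * ppd
  cy <- (height + 1) / 2 - spec$center_y * ppd
  dx <- (matrix(rep(seq_len(width), each = height), height, width) - cx) / ppd
  dy <- (matrix(rep(seq_len(height), times = width), height, width) - cy) / ppd
  sqrt(dx^2 + dy^2)
}

# Check that the full support (r + w) fits inside the field.
check_window_fits <- function(height, width, spec, ppd) {
  sup <- (spec$r + spec$w) * ppd
  cx <- (width + 1) / 2 + spec$center_x * ppd
  cy <- (height + 1) / 2 - spec$center_y * ppd
  if (cx - sup < 0.5 || cx + sup > width + 0.5 ||
      cy - sup < 0.5 || cy + sup > height + 0.5) {
    stop(sprintf(
      "window support (r + w = %g deg = %g px) around center (%g, %g) deg does not fit a %d x %d field",
      spec$r + spec$w, sup, spec$center_x, spec$center_y, height, width),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' Raised-cosine window weight map
#'
#' Radially symmetric weights: 1 for distance `d <= r`, 0 for
#' `d >= r + w`, and `0.5 * (1 + cos(pi * (d - r) / w))` on the ramp.
#'
#' @param height,width Field dimensions in pixels.
#' @param spec A [window_spec()].
#' @param ppd Pixels per degree of visual angle.
#' @return Matrix of weights in `[0, 1]`.
#' @export
raised_cosine_window <- function(height, width, spec, ppd) {
  stopifnot(inherits(spec, "window_spec"), ppd > 0)
  check_window_fits(height, width, spec, ppd)
  d <- window_distance_map(height, width, spec, ppd)
  w <- matrix(0, height, width)
  w[d <= spec$r] <- 1
  if (spec$w > 0) {
    ramp <- d > spec$r & d < spec$r + spec$w
    w[ramp] <- 0.5 * (1 + cos(pi * (d[ramp] - spec$r) / spec$w))
  }
  w
}

#' Embed a signal image into a background through a soft window
#'
#' Pointwise convex combination `W * signal + (1 - W) * background` with
#' `W` the raised-cosine window: the composite equals the background
#' bit-exactly outside the window support, equals the signal bit-exactly on
#' the plateau, and introduces no overshoot anywhere. The signal is the
#' whole-field filtered image (normally amplitude-matched to the background
#' first); only its windowed subpart enters the composite.
#'
#' @param background,signal `noise_field`s or matrices of equal dimensions.
#' @param spec A [window_spec()].
#' @param ppd Pixels per degree.
#' @return A `noise_field` holding the composite (background metadata
#'   retained).
#' @export
embed_signal <- function(background, signal, spec, ppd) {
  bg <- field_pixels(background)
  sg <- field_pixels(signal)
  if (!all(dim(bg) == dim(sg))) {
    stop("`background` and `signal` must share dimensions", call. = FALSE)
  }
  w <- raised_cosine_window(nrow(bg), ncol(bg), spec, ppd)
  comp <- bg
  inside <- w > 0
  comp[inside] <- w[inside] * sg[inside] + (1 - w[inside]) * bg[inside]
  plateau <- w >= 1
  comp[plateau] <- sg[plateau]
  if (inherits(background, "noise_field")) {
    background$pixels <- comp
    background
  } else {
    new_noise_field(comp, mean(bg), NA_real_)
  }
}

#' Soft field aperture for the noise background
#'
#' Field-level mask: a circular raised-cosine aperture (plateau radius
#' `radius`, ramp `ramp`) or a hard rectangle of the given height/width, in
#' degrees. Used to confine the displayed noise field (e.g. a circular
#' full-screen field or a narrow horizontal strip); applied at
#' export/display time against the mean luminance.
#'
#' @param height,width Field dimensions in pixels.
#' @param ppd Pixels per degree.
#' @param shape `"circular"` or `"rectangular"`.
#' @param radius Plateau radius in degrees (circular).
#' @param ramp Cosine ramp width in degrees (circular).
#' @param rect_height,rect_width Rectangle dimensions in degrees
#'   (rectangular).
#' @return Matrix of weights in `[0, 1]`.
#' @export
field_shape_mask <- function(height, width, ppd, shape = c("circular", "rectangular"),
                             radius = NULL, ramp = 0,
                             rect_height = NULL, rect_width = NULL) {
  shape <- match.arg(shape)
  if (shape == "circular") {
    stopifnot(!is.null(radius))
    d <- window_distance_map(height, width, window_spec(0, 0, radius, max(ramp, 0)), ppd)
    m <- matrix(0, height, width)
    m[d <= radius] <- 1
    if (ramp > 0) {
      on_ramp <- d > radius & d < radius + ramp
      m[on_ramp] <- 0.5 * (1 + cos(pi * (d[on_ramp] - radius) / ramp))
    }
    m
  } else {
    stopifnot(!is.null(rect_height), !is.null(rect_width))
    ys <- abs((seq_len(height) - (height + 1) / 2) / ppd)
    xs <- abs((seq_len(width) - (width + 1) / 2) / ppd)
    outer(as.numeric(ys <= rect_height / 2), as.numeric(xs <= rect_width / 2))
  }
}

#' Apply a field mask against mean luminance
#'
#' Display composition step: `mean + mask * (pixels - mean)`, leaving the
#' masked-out surround at the uniform background luminance.
#'
#' @param pixels Image matrix.
#' @param mask Weight matrix in `[0, 1]` (same dimensions).
#' @param mean_luminance Background gray level.
#' @return Masked image matrix.
#' @export
apply_shape_mask <- function(pixels, mask, mean_luminance) {
  stopifnot(all(dim(pixels) == dim(mask)))
  mean_luminance + mask * (pixels - mean_luminance)
}
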