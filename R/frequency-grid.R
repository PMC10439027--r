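#' Discrete Fourier frequency coordinates for an image
#'
#' Builds the frequency-domain coordinate grid matching [stats::fft()]'s
#' layout for a `height` x `width` real image: horizontal frequency `fx`
#' (cycles per image along x / columns), vertical frequency `fy` (cycles per
#' image along y / rows), radial frequency `fr = sqrt(fx^2 + fy^2)`, and
#' orientation angle `phi = arctan(fy / fx)` in degrees.
#'
#' Grid convention (used consistently across the package): matrix element
#' `[i, j]` holds the DFT coefficient for vertical frequency index `i - 1`
#' and horizontal index `j - 1`, with indices above `floor(n/2)` wrapping to
#' negative frequencies (the standard FFT ordering). `phi` is an orientation,
#' not a direction: it is folded into the 180-degree-periodic canonical range
#' `[-90, +90)`. `phi = 0` corresponds to energy along the horizontal
#' frequency axis, i.e. vertically oriented image structure. `phi` is
#' undefined (NA) at DC.
#'
#' @param height,width Image dimensions in pixels (each >= 2).
#' @return An object of class `frequency_grid`: a list with matrices `fx`,
#'   `fy`, `fr`, `phi` (all `height` x `width`), the scalar `nyquist`
#'   (`min(height, width) / 2`, cycles per image), and `dim`.
#' @export
make_frequency_grid <- function(height, width) {
  if (!is.numeric(height) || !is.numeric(width) ||
      length(height) != 1L || length(width) != 1L ||
      height < 2 || width < 2 || height != round(height) || width != round(width)) {
    stop("`height` and `width` must be integers >= 2", call. = FALSE)
  }
  height <- as.integer(height)
  width <- as.integer(width)
  fx <- matrix(rep(fft_freqs(width), each = height), height, width)
  fy <- matrix(rep(fft_freqs(height), times = width), height, width)
  fr <- sqrt(fx^2 + fy^2)
  phi <- fold_orientation(atan2(fy, fx) * 180 / pi)
  phi[1L, 1L] <- NA_real_
  structure(
    list(fx = fx, fy = fy, fr = fr, phi = phi,
         nyquist = min(height, width) / 2,
         dim = c(height, width)),
    class = "frequency_grid"
  )
}

# Integer DFT frequencies in cycles/image, FFT ordering:
# 0, 1, ..., floor((n-1)/2), -floor(n/2), ..., -1
fft_freqs <- function(n) {
  c(0:((n - 1L) %/% 2L), -(n %/% 2L):-1L)
}

# Fold angles (degrees) into the canonical orientation range [-90, 90).
fold_orientation <- function(deg) {
  ((deg + 90) %% 180) - 90
}

# Minimal angular distance between two orientations under 180-degree
# periodicity; result in [0, 90].
orientation_distance <- function(phi, phi0) {
  d <- abs(phi - phi0) %% 180
  pmin(d, 180 - d)
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid %d x %d, Nyquist %.1f cycles/image>\n",
              x$dim[1], x$dim[2], x$nyquist))
  invisible(x)
}
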