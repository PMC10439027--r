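#' Seeded 2-D pink-noise image
#'
#' Synthesizes a real-valued luminance image whose amplitude spectrum falls
#' off as 1/f (pink noise), matching the second-order statistics of natural
#' scenes. Construction is in the frequency domain: a white Gaussian image is
#' Fourier transformed (which yields independent complex-Gaussian
#' coefficients with Hermitian symmetry), its amplitudes are scaled by
#' `1/fr`, and the inverse transform is taken. The DC coefficient is zeroed
#' (1/fr is singular there); the requested mean is imposed by the final
#' normalization, which fixes the sample mean to `mean_luminance` and the
#' sample RMS contrast (population SD divided by mean luminance) to
#' `contrast`.
#'
#' @param height,width Image dimensions in pixels (each >= 16; spectral
#'   diagnostics are meaningless below that).
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   pixels.
#' @param mean_luminance Target mean, in normalized luminance units
#'   (0 = black, 1 = white). Default 0.5.
#' @param contrast Target RMS contrast (SD / mean), > 0. Default 0.2.
#' @param shape_mask Optional field-level soft mask in `[0, 1]` (same
#'   dimensions), e.g. a circular or rectangular field aperture. The mask is
#'   carried as metadata and applied at export/display time; stored pixels
#'   remain full-field so their statistics stay exactly on target.
#' @return An object of class `noise_field`: list with `pixels` (matrix),
#'   `mean_luminance`, `contrast`, `seed`, `shape_mask`.
#' @export
generate_pink_noise <- function(height, width, seed,
                                mean_luminance = 0.5, contrast = 0.2,
                                shape_mask = NULL) {
  if (height < 16 || width < 16) {
    stop("pink-noise fields must be at least 16 x 16 pixels", call. = FALSE)
  }
  if (!is.numeric(contrast) || contrast <= 0) {
    stop("`contrast` must be > 0", call. = FALSE)
  }
  if (!is.null(shape_mask)) {
    stopifnot(is.matrix(shape_mask), all(dim(shape_mask) == c(height, width)))
  }
  grid <- make_frequency_grid(height, width)
  white <- with_seed(seed, matrix(stats::rnorm(height * width), height, width))
  spec <- stats::fft(white)
  scale <- 1 / grid$fr
  scale[1L, 1L] <- 0 # DC: singular; mean re-imposed by normalization
  pink <- Re(stats::fft(spec * scale, inverse = TRUE)) / (height * width)
  pixels <- normalize_pixels(pink, mean_luminance, contrast)
  new_noise_field(pixels, mean_luminance, contrast, seed, shape_mask)
}

new_noise_field <- function(pixels, mean_luminance, contrast, seed = NA_integer_,
                            shape_mask = NULL) {
  structure(
    list(pixels = pixels, mean_luminance = mean_luminance,
         contrast = contrast, seed = seed, shape_mask = shape_mask),
    class = "noise_field"
  )
}

#' @export
print.noise_field <- function(x, ...) {
  cat(sprintf("<noise_field %d x %d, mean %.3g, RMS contrast %.3g, seed %s>\n",
              nrow(x$pixels), ncol(x$pixels), mean(x$pixels),
              stats::sd(c(x$pixels)) * sqrt((length(x$pixels) - 1) / length(x$pixels)) / mean(x$pixels),
              format(x$seed)))
  invisible(x)
}

# Extract the pixel matrix from a noise_field or plain matrix.
field_pixels <- function(x) {
  if (inherits(x, "noise_field")) x$pixels
  else if (is.matrix(x)) x
  else stop("expected a noise_field or a matrix", call. = FALSE)
}

#' Impose mean luminance and RMS contrast by an affine transform
#'
#' Maps `x` to `a * x + b` such that the sample mean equals
#' `mean_luminance` and the population SD equals
#' `contrast * mean_luminance` (RMS contrast = SD / mean). Idempotent:
#' applying it twice equals applying it once.
#'
#' @param x Numeric matrix (non-constant).
#' @param mean_luminance,contrast Targets as in [generate_pink_noise()].
#' @return The rescaled matrix.
#' @export
normalize_pixels <- function(x, mean_luminance, contrast) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) {
    stop("cannot normalize a constant image (zero contrast)", call. = FALSE)
  }
  (x - m) * (contrast * mean_luminance / s) + mean_luminance
}

# Amplitude spectrum of a field's pixels.
amplitude_spectrum <- function(x) {
  Mod(stats::fft(field_pixels(x)))
}

#' Radially averaged amplitude profile
#'
#' Diagnostic for the 1/f property: partitions the radial frequency range
#' `(0, Nyquist]` into bins and averages the amplitude spectrum within each.
#' DC is excluded.
#'
#' @param field A `noise_field` or matrix.
#' @param n_bins Number of bins (>= 4).
#' @param spacing `"linear"` or `"log2"` bin edges.
#' @return Data frame with columns `f` (mean radial frequency per bin,
#'   cycles/image), `amplitude` (mean amplitude), `n` (coefficients per
#'   bin). Empty bins are dropped.
#' @export
radial_amplitude_profile <- function(field, n_bins = 32, spacing = c("linear", "log2")) {
  spacing <- match.arg(spacing)
  if (n_bins < 4) stop("`n_bins` must be >= 4", call. = FALSE)
  px <- field_pixels(field)
  grid <- make_frequency_grid(nrow(px), ncol(px))
  amp <- amplitude_spectrum(px)
  keep <- grid$fr > 0 & grid$fr <= grid$nyquist
  fr <- grid$fr[keep]
  a <- amp[keep]
  edges <- switch(spacing,
    linear = seq(0, grid$nyquist, length.out = n_bins + 1L),
    log2 = c(0, 2^seq(log2(min(fr)), log2(grid$nyquist), length.out = n_bins))
  )
  bin <- cut(fr, edges, include.lowest = FALSE, right = TRUE)
  out <- data.frame(
    f = as.numeric(tapply(fr, bin, mean)),
    amplitude = as.numeric(tapply(a, bin, mean)),
    n = as.integer(tapply(a, bin, length))
  )
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Log-log slope of the radial amplitude profile
#'
#' Least-squares slope of `log(amplitude)` against `log(f)` over log2-spaced
#' radial bins, weighted by the number of Fourier coefficients per bin (the
#' sampling variance of a bin's log amplitude scales inversely with its
#' coefficient count, so low-frequency bins with a handful of coefficients
#' are down-weighted accordingly). The lowest and highest half-octave are
#' excluded from the fit (discretization artifacts at both spectral
#' edges). Pink noise has slope -1.
#'
#' @param field A `noise_field` or matrix.
#' @param n_bins Number of log2-spaced bins used before edge trimming.
#' @return The fitted slope (dimensionless).
#' @export
spectral_slope <- function(field, n_bins = 24) {
  prof <- radial_amplitude_profile(field, n_bins = n_bins, spacing = "log2")
  px <- field_pixels(field)
  nyq <- min(dim(px)) / 2
  lo <- min(prof$f) * sqrt(2)
  hi <- nyq / sqrt(2)
  prof <- prof[prof$f >= lo & prof$f <= hi, , drop = FALSE]
  if (nrow(prof) < 3) stop("too few radial bins for a slope fit", call. = FALSE)
  unname(stats::coef(stats::lm(log(amplitude) ~ log(f), data = prof,
                               weights = prof$n))[2])
}

#' Spectral energy in a radial frequency band
#'
#' Sum of squared Fourier amplitudes over coefficients with radial frequency
#' in `[f_lo, f_hi)`. For 1/f noise, bands one octave wide carry equal
#' energy in expectation — the scale-invariance property that makes the
#' stimulus equally discriminable across retinal eccentricities.
#'
#' @param field A `noise_field` or matrix.
#' @param f_lo,f_hi Band edges in cycles/image, `0 < f_lo < f_hi <= Nyquist`.
#' @return Scalar energy (squared amplitude units).
#' @export
band_energy <- function(field, f_lo, f_hi) {
  px <- field_pixels(field)
  nyq <- min(dim(px)) / 2
  if (!(f_lo > 0 && f_lo < f_hi && f_hi <= nyq)) {
    stop(sprintf("band edges must satisfy 0 < f_lo < f_hi <= Nyquist (%g)", nyq),
         call. = FALSE)
  }
  grid <- make_frequency_grid(nrow(px), ncol(px))
  amp <- amplitude_spectrum(px)
  sum(amp[grid$fr >= f_lo & grid$fr < f_hi]^2)
}

#' Energy ratio of two adjacent octaves
#'
#' Convenience diagnostic: `band_energy(f, 2f) / band_energy(2f, 4f)`.
#' Equals 1 in expectation for pink noise.
#'
#' @param field A `noise_field` or matrix.
#' @param f_base Lower edge of the first octave (cycles/image); `4 * f_base`
#'   must not exceed Nyquist.
#' @return Scalar ratio.
#' @export
octave_energy_ratio <- function(field, f_base) {
  band_energy(field, f_base, 2 * f_base) / band_energy(field, 2 * f_base, 4 * f_base)
}
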