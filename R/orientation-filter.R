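#' Orientation filter specification
#'
#' Parameters of the Gaussian angular weighting that carves the local
#' orientation signal out of the pink-noise spectrum: the preferred
#' orientation `phi0` (degrees; an orientation, interpreted modulo 180) and
#' the filter width `sigma` (degrees, > 0). Narrower `sigma` concentrates
#' spectral energy around `phi0` and yields a stronger, more discriminable
#' signal; the filter is flat along the radial direction, so the 1/f
#' characteristic of the noise is retained.
#'
#' @param phi0 Preferred orientation in degrees (e.g. +40 or -40 from
#'   vertical).
#' @param sigma Angular width in degrees, > 0 (typical task range 30-70).
#' @return An object of class `orientation_filter_spec`.
#' @export
orientation_filter_spec <- function(phi0, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a positive scalar (degrees)", call. = FALSE)
  }
  if (!is.numeric(phi0) || length(phi0) != 1L) {
    stop("`phi0` must be a scalar orientation in degrees", call. = FALSE)
  }
  structure(list(phi0 = phi0, sigma = sigma), class = "orientation_filter_spec")
}

#' @export
print.orientation_filter_spec <- function(x, ...) {
  cat(sprintf("<orientation_filter_spec phi0 = %g deg, sigma = %g deg>\n",
              x$phi0, x$sigma))
  invisible(x)
}

#' Gaussian orientation weight map
#'
#' Frequency-domain weights `exp(-(dphi / sigma)^2)`, where `dphi` is the
#' minimal angular distance between each coefficient's orientation `phi` and
#' the preferred orientation `phi0` under 180-degree periodicity. The DC
#' weight is defined as 1 so that the image mean passes through untouched.
#' Because folded orientation is even under frequency negation, the map is
#' Hermitian-compatible and filtering a real image returns a real image.
#'
#' The Gaussian is not wrapped (no sum over 180-degree periods): for
#' `sigma = 70` the tail at the 90-degree fold is `exp(-(90/70)^2)` (about
#' 0.19), which is kept deliberately — the filter is the plain Gaussian of
#' the protocol's definition.
#'
#' On even-sized grids the Nyquist row/column is aliased: frequency `-N/2`
#' and `+N/2` coincide, so those bins carry two orientation readings. The
#' weight there is the average of the Gaussian at both readings, which is
#' the unique choice consistent with Hermitian symmetry (and hence a real
#' filtered image).
#'
#' @param grid A [make_frequency_grid()] object.
#' @param spec An [orientation_filter_spec()].
#' @return Matrix of weights in `[0, 1]` with the grid's dimensions.
#' @export
orientation_weight_map <- function(grid, spec) {
  stopifnot(inherits(grid, "frequency_grid"), inherits(spec, "orientation_filter_spec"))
  d <- orientation_distance(grid$phi, spec$phi0)
  w <- exp(-(d / spec$sigma)^2)
  w[1L, 1L] <- 1
  # Aliased Nyquist bins (even dims): average the weight over the two
  # coincident frequencies +/-N/2 so that w(f) == w(-f) exactly.
  h <- nrow(w); wd <- ncol(w)
  neg <- function(n) c(1L, rev(seq_len(n - 1L) + 1L))
  (w + w[neg(h), neg(wd)]) / 2
}

#' Apply the orientation filter to a noise field
#'
#' Multiplies the field's Fourier transform by the Gaussian orientation
#' weight map and inverts. The operation only reweights angular energy: the
#' radially averaged amplitude profile remains proportional to 1/f, while
#' orientation energy concentrates around `phi0`. The output is not
#' re-normalized; use [match_amplitude_range()] before embedding.
#'
#' @param field A `noise_field` (or matrix).
#' @param spec An [orientation_filter_spec()].
#' @return A `noise_field` with filtered pixels and the same target
#'   statistics metadata.
#' @export
apply_orientation_filter <- function(field, spec) {
  px <- field_pixels(field)
  grid <- make_frequency_grid(nrow(px), ncol(px))
  w <- orientation_weight_map(grid, spec)
  out <- stats::fft(stats::fft(px) * w, inverse = TRUE) / length(px)
  resid <- max(abs(Im(out)))
  rms <- sqrt(mean(Re(out)^2))
  if (rms > 0 && resid > 1e-8 * rms) {
    stop("orientation filtering produced a non-real image; grid symmetry broken",
         call. = FALSE)
  }
  f <- if (inherits(field, "noise_field")) field else new_noise_field(px, mean(px), NA_real_)
  f$pixels <- Re(out)
  f$filter <- spec
  f
}

#' Rescale an image to the amplitude range of a reference
#'
#' Affine (order-preserving) rescale of `filtered` so that its minimum and
#' maximum equal those of `reference` exactly — the normalization applied to
#' the orientation-filtered image before it is embedded into the unfiltered
#' background.
#'
#' @param filtered A `noise_field` or matrix (non-constant).
#' @param reference A `noise_field` or matrix with the same dimensions.
#' @return Object of the same kind as `filtered` with rescaled pixels.
#' @export
match_amplitude_range <- function(filtered, reference) {
  fx <- field_pixels(filtered)
  rx <- field_pixels(reference)
  if (!all(dim(fx) == dim(rx))) {
    stop("`filtered` and `reference` must share dimensions", call. = FALSE)
  }
  fr <- range(fx)
  if (fr[1] == fr[2]) {
    stop("`filtered` is constant; amplitude range is degenerate", call. = FALSE)
  }
  rr <- range(rx)
  out <- (fx - fr[1]) / (fr[2] - fr[1]) * (rr[2] - rr[1]) + rr[1]
  if (inherits(filtered, "noise_field")) {
    filtered$pixels <- out
    filtered
  } else {
    out
  }
}

#' Orientation-band energy of an image
#'
#' Sum of squared Fourier amplitudes over coefficients whose orientation
#' lies within `half_width` degrees of `phi0` (180-degree-periodic
#' distance), DC excluded. Used by the image-computable decoder and by
#' orientation-selectivity diagnostics.
#'
#' @param field A `noise_field` or matrix.
#' @param phi0 Band center orientation in degrees.
#' @param half_width Band half-width in degrees.
#' @return Scalar energy.
#' @export
orientation_band_energy <- function(field, phi0, half_width = 15) {
  px <- field_pixels(field)
  grid <- make_frequency_grid(nrow(px), ncol(px))
  amp <- amplitude_spectrum(px)
  sel <- !is.na(grid$phi) & orientation_distance(grid$phi, phi0) <= half_width
  sum(amp[sel]^2)
}
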