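#' Keyframe stream for a dynamic noise movie
#'
#' An ordered set of seeded pink-noise keyframes (A, B, C, ...) to be
#' connected by `n_steps` statistics-adjusted hybrid frames per pair at a
#' given update rate. All keyframes must share dimensions and target
#' statistics.
#'
#' @param keyframes List of `noise_field`s (>= 2).
#' @param n_steps Hybrid steps between successive keyframes (>= 1; the
#'   protocol's default is 4).
#' @param update_rate Noise update rate in Hz (e.g. 60).
#' @return An object of class `keyframe_stream`.
#' @export
keyframe_stream <- function(keyframes, n_steps = 4, update_rate = 60) {
  if (length(keyframes) < 2) stop("need at least 2 keyframes", call. = FALSE)
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  dims <- lapply(keyframes, function(k) dim(field_pixels(k)))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all keyframes must share dimensions", call. = FALSE)
  }
  m <- unique(vapply(keyframes, function(k) k$mean_luminance, numeric(1)))
  ct <- unique(vapply(keyframes, function(k) k$contrast, numeric(1)))
  if (length(m) != 1L || length(ct) != 1L) {
    stop("all keyframes must share target mean and contrast", call. = FALSE)
  }
  structure(
    list(keyframes = keyframes, n_steps = as.integer(n_steps),
         update_rate = update_rate, mean_luminance = m, contrast = ct),
    class = "keyframe_stream"
  )
}

#' Generate a seeded keyframe stream
#'
#' Convenience constructor: draws `n_keyframes` independent pink-noise
#' fields from per-keyframe substreams of `seed`.
#'
#' @param n_keyframes Number of keyframes (>= 2).
#' @param height,width Field dimensions in pixels.
#' @param seed Master seed for the stream.
#' @inheritParams generate_pink_noise
#' @inheritParams keyframe_stream
#' @return A `keyframe_stream`.
#' @export
make_keyframe_stream <- function(n_keyframes, height, width, seed,
                                 mean_luminance = 0.5, contrast = 0.2,
                                 n_steps = 4, update_rate = 60,
                                 shape_mask = NULL) {
  kf <- lapply(seq_len(n_keyframes), function(i) {
    generate_pink_noise(height, width, substream_seed(seed, "noise", i),
                        mean_luminance, contrast, shape_mask = shape_mask)
  })
  keyframe_stream(kf, n_steps = n_steps, update_rate = update_rate)
}

#' Hybrid frames between two noise images
#'
#' Linear pixel mixes of keyframes A and B: step `k` of `n` has weights
#' `((n - k) / n, k / n)` for `k = 1 .. n-1` (the AAB / AB / ABB
#' compositional reading, generalized), followed by the endpoint B, giving
#' `n` images in total. Each hybrid is re-adjusted to the reference mean and
#' contrast, since averaging two independent noises lowers RMS contrast
#' (by about 1/sqrt(2) at the midpoint).
#'
#' @param A,B `noise_field`s or matrices of equal dimensions.
#' @param n_steps Number of steps `n` (>= 1).
#' @param reference_mean,reference_contrast Target statistics; default to
#'   A's metadata when A is a `noise_field`.
#' @return List of `n_steps` pixel matrices (the last is B, statistics
#'   re-imposed).
#' @export
interpolate_keyframes <- function(A, B, n_steps,
                                  reference_mean = NULL, reference_contrast = NULL) {
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  a <- field_pixels(A)
  b <- field_pixels(B)
  if (!all(dim(a) == dim(b))) stop("A and B must share dimensions", call. = FALSE)
  if (is.null(reference_mean)) {
    reference_mean <- if (inherits(A, "noise_field")) A$mean_luminance else mean(a)
  }
  if (is.null(reference_contrast)) {
    reference_contrast <- if (inherits(A, "noise_field")) A$contrast
      else sqrt(mean((a - mean(a))^2)) / mean(a)
  }
  lapply(seq_len(n_steps), function(k) {
    mix <- ((n_steps - k) / n_steps) * a + (k / n_steps) * b
    adjust_image_statistics(mix, reference_mean, reference_contrast)
  })
}

#' Re-impose image statistics on a hybrid frame
#'
#' Affine per-image transform fixing the sample mean to `reference_mean`
#' and the RMS contrast to `reference_contrast` — the adjustment that keeps
#' hybrid frames statistically indistinguishable from the keyframes (no
#' global luminance or contrast flicker). Idempotent.
#'
#' @param hybrid Image matrix (non-constant) or `noise_field`.
#' @param reference_mean Target mean luminance.
#' @param reference_contrast Target RMS contrast.
#' @return Adjusted pixel matrix (or `noise_field` if given one).
#' @export
adjust_image_statistics <- function(hybrid, reference_mean, reference_contrast) {
  px <- field_pixels(hybrid)
  out <- normalize_pixels(px, reference_mean, reference_contrast)
  if (inherits(hybrid, "noise_field")) {
    hybrid$pixels <- out
    hybrid$mean_luminance <- reference_mean
    hybrid$contrast <- reference_contrast
    hybrid
  } else {
    out
  }
}

# Expand a keyframe_stream into raw background frames:
# [A, hybrids(A->B), B, hybrids(B->C), C, ...]; pure A appears once.
expand_stream_frames <- function(stream) {
  kf <- lapply(stream$keyframes, field_pixels)
  frames <- list(adjust_image_statistics(kf[[1]], stream$mean_luminance, stream$contrast))
  for (i in seq_len(length(kf) - 1L)) {
    frames <- c(frames, interpolate_keyframes(
      kf[[i]], kf[[i + 1L]], stream$n_steps,
      stream$mean_luminance, stream$contrast))
  }
  frames
}

# Convert a duration in seconds to a whole number of frames at `rate` Hz,
# failing loudly (with the nearest valid durations) on misalignment.
seconds_to_frames <- function(seconds, rate, what = "duration") {
  n <- seconds * rate
  if (abs(n - round(n)) > 1e-6) {
    lo <- floor(n) / rate * 1000
    hi <- ceiling(n) / rate * 1000
    stop(sprintf(
      "%s of %g ms is not a whole number of frames at %g Hz; nearest valid: %.4g ms (%d frames) or %.4g ms (%d frames)",
      what, seconds * 1000, rate, lo, floor(n), hi, ceiling(n)),
      call. = FALSE)
  }
  as.integer(round(n))
}

#' Frame sequence with event annotations
#'
#' Container for an ordered stimulus movie: grayscale frames, per-frame
#' event annotations (`cue_on`, `cue_off`, `signal_on`, `signal_off`,
#' `mask_on`), the frame period, and target statistics. Construct with
#' [build_dynamic_stimulus()] or [build_trial()].
#'
#' @param frames List of pixel matrices.
#' @param events Data frame with columns `frame` (1-based index), `t_ms`,
#'   `label`.
#' @param update_rate Hz.
#' @param mean_luminance,contrast Target statistics shared by every frame.
#' @param repeat_factor Display repeats per unique frame (e.g. 2 when a
#'   60 Hz stimulus runs on a 120 Hz display).
#' @param shape_mask Optional field aperture, applied at export time.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, events, update_rate,
                           mean_luminance, contrast,
                           repeat_factor = 1L, shape_mask = NULL) {
  stopifnot(is.list(frames), is.data.frame(events))
  if (nrow(events) && (any(events$frame < 1) || any(events$frame > length(frames) + 1L))) {
    stop("event frame indices out of range", call. = FALSE)
  }
  structure(
    list(frames = frames, events = events, update_rate = update_rate,
         frame_period = 1 / update_rate,
         mean_luminance = mean_luminance, contrast = contrast,
         repeat_factor = as.integer(repeat_factor), shape_mask = shape_mask),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence %d frames @ %g Hz (%d x %d px), %d events>\n",
              length(x$frames), x$update_rate,
              nrow(x$frames[[1]]), ncol(x$frames[[1]]), nrow(x$events)))
  invisible(x)
}

# First/last signal frame indices from the event table (NULL if absent).
signal_frame_range <- function(sequence) {
  ev <- sequence$events
  on <- ev$frame[ev$label == "signal_on"]
  off <- ev$frame[ev$label == "signal_off"]
  if (!length(on) || !length(off)) return(NULL)
  c(on[1], off[1] - 1L)
}

#' Build a dynamic stimulus movie with an embedded orientation signal
#'
#' Expands a keyframe stream into background frames and, over the signal
#' interval, replaces each frame's windowed region with the
#' orientation-filtered version of that same frame (filtered per frame, not
#' a static patch): filter, match the amplitude range of the unfiltered
#' frame, embed through the raised-cosine window, then re-impose the global
#' mean and contrast. Because the background keeps stepping underneath and
#' all frames share identical statistics, signal onset and offset are
#' concealed by the continuous full-field changes.
#'
#' @param stream A [keyframe_stream()].
#' @param signal_spec [orientation_filter_spec()] or NULL for a pure
#'   background movie.
#' @param window [window_spec()] for the embedded signal.
#' @param signal_onset Signal onset in seconds from movie start; must be a
#'   whole number of frames at the update rate.
#' @param signal_duration Signal duration in seconds; whole frames, >= 1.
#' @param ppd Pixels per degree.
#' @param cue Optional list `list(onset, duration)` in seconds (whole
#'   frames); annotated as `cue_on`/`cue_off` events at the signal window's
#'   location (rendered at export time).
#' @return A [frame_sequence()].
#' @export
build_dynamic_stimulus <- function(stream, signal_spec = NULL, window = NULL,
                                   signal_onset = 0, signal_duration = 0,
                                   ppd = NULL, cue = NULL) {
  stopifnot(inherits(stream, "keyframe_stream"))
  frames <- expand_stream_frames(stream)
  n_frames <- length(frames)
  rate <- stream$update_rate
  events <- data.frame(frame = integer(), t_ms = numeric(), label = character())
  add_event <- function(frame, label) {
    rbind(events, data.frame(frame = frame, t_ms = (frame - 1L) / rate * 1000,
                             label = label))
  }
  if (!is.null(signal_spec)) {
    stopifnot(inherits(signal_spec, "orientation_filter_spec"),
              inherits(window, "window_spec"), !is.null(ppd))
    on_f <- seconds_to_frames(signal_onset, rate, "signal onset") + 1L
    n_sig <- seconds_to_frames(signal_duration, rate, "signal duration")
    if (n_sig < 1) stop("`signal_duration` must cover at least one frame", call. = FALSE)
    if (on_f < 1L || on_f + n_sig - 1L > n_frames) {
      stop(sprintf("signal interval (frames %d-%d) lies outside the %d-frame movie",
                   on_f, on_f + n_sig - 1L, n_frames), call. = FALSE)
    }
    for (k in on_f:(on_f + n_sig - 1L)) {
      filtered <- apply_orientation_filter(frames[[k]], signal_spec)
      matched <- match_amplitude_range(field_pixels(filtered), frames[[k]])
      comp <- embed_signal(frames[[k]], matched, window, ppd)
      frames[[k]] <- adjust_image_statistics(field_pixels(comp),
                                             stream$mean_luminance, stream$contrast)
    }
    events <- add_event(on_f, "signal_on")
    events <- add_event(on_f + n_sig, "signal_off")
    if (on_f + n_sig <= n_frames) events <- add_event(on_f + n_sig, "mask_on")
  }
  if (!is.null(cue)) {
    c_on <- seconds_to_frames(cue$onset, rate, "cue onset") + 1L
    c_n <- seconds_to_frames(cue$duration, rate, "cue duration")
    if (c_on < 1L || c_on + c_n - 1L > n_frames) {
      stop("cue interval lies outside the movie", call. = FALSE)
    }
    events <- add_event(c_on, "cue_on")
    events <- add_event(c_on + c_n, "cue_off")
  }
  events <- events[order(events$frame), , drop = FALSE]
  rownames(events) <- NULL
  sm <- stream$keyframes[[1]]$shape_mask
  frame_sequence(frames, events, rate, stream$mean_luminance, stream$contrast,
                 shape_mask = sm)
}

#' Temporal concealment diagnostic
#'
#' Ratio of the mean frame-to-frame RMS difference within the signal
#' interval to that outside it. Values near 1 mean the local signal's
#' appearance and disappearance are hidden inside the ongoing full-field
#' changes (no transient jump that could capture attention).
#'
#' @param sequence A [frame_sequence()] containing signal events.
#' @return List with `ratio`, `rms` (per-transition RMS differences) and
#'   `signal_transitions` (logical, TRUE where either endpoint is a signal
#'   frame).
#' @export
concealment_ratio <- function(sequence) {
  rng <- signal_frame_range(sequence)
  if (is.null(rng)) stop("sequence has no signal events", call. = FALSE)
  n <- length(sequence$frames)
  if (n < 3) stop("need at least 3 frames", call. = FALSE)
  rms <- vapply(seq_len(n - 1L), function(k) {
    sqrt(mean((sequence$frames[[k + 1L]] - sequence$frames[[k]])^2))
  }, numeric(1))
  # transition k connects frames k and k+1
  in_sig <- vapply(seq_len(n - 1L), function(k) {
    (k >= rng[1] && k <= rng[2]) || (k + 1L >= rng[1] && k + 1L <= rng[2])
  }, logical(1))
  if (!any(in_sig) || all(in_sig)) {
    stop("signal interval must leave both signal and background transitions", call. = FALSE)
  }
  list(ratio = mean(rms[in_sig]) / mean(rms[!in_sig]),
       rms = rms, signal_transitions = in_sig)
}
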