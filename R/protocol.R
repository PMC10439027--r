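#' Session configuration
#'
#' Validated bundle of everything needed to reproduce an experimental
#' session: display geometry, noise-field parameters, signal window and
#' filter ladder, placement mode, timing table, trial counts and the master
#' seed. Construct from a named list (see the shipped YAML fixtures
#' `exp1a.yaml` and `exp2.yaml` under `inst/extdata` for the schema) or via
#' [load_config()].
#'
#' Required structure (all durations in ms, all sizes in degrees unless
#' suffixed `_px`):
#' \describe{
#'   \item{schema_version}{Integer, currently 1.}
#'   \item{display}{`width_px`, `height_px`, `ppd`, `refresh_hz`.}
#'   \item{noise}{`update_rate` (Hz), `n_steps`, `mean_luminance`,
#'     `contrast`, `field_px` (height, width), `shape`
#'     ("circular"/"rectangular") plus `field_radius_deg`/`field_ramp_deg`
#'     or `field_height_deg`/`field_width_deg`.}
#'   \item{signal}{`r_deg`, `w_deg`, `tilts_deg`, `sigma_ladder_deg`.}
#'   \item{placement}{`mode` ("eccentricity"/"position"), `values_deg`.}
#'   \item{timing_ms}{`fixation_min`, `fixation_max`, `cue`,
#'     `cue_signal_delay`, `signal`, `mask`.}
#'   \item{trials}{`n_trials`, `conditions`.}
#'   \item{seed}{Master seed.}
#' }
#'
#' @param config Named list with the fields above.
#' @return An object of class `session_config`.
#' @export
session_config <- function(config) {
  # YAML sequences of mixed int/float arrive as lists; flatten numeric fields.
  for (blk in list(c("noise", "field_px"), c("signal", "tilts_deg"),
                   c("signal", "sigma_ladder_deg"), c("placement", "values_deg"))) {
    v <- config[[blk[1]]][[blk[2]]]
    if (!is.null(v) && is.list(v)) config[[blk[1]]][[blk[2]]] <- as.numeric(unlist(v))
  }
  errs <- character()
  need <- function(path, test = NULL, msg = NULL) {
    x <- config
    for (k in path) {
      if (!is.list(x) || is.null(x[[k]])) {
        errs <<- c(errs, sprintf("missing field: %s", paste(path, collapse = "$")))
        return(invisible(NULL))
      }
      x <- x[[k]]
    }
    if (!is.null(test) && !isTRUE(test(x))) {
      errs <<- c(errs, sprintf("invalid field %s: %s", paste(path, collapse = "$"), msg))
    }
    invisible(x)
  }
  need("schema_version", function(v) v == 1, "unsupported schema version")
  need(c("display", "width_px"))
  need(c("display", "height_px"))
  need(c("display", "ppd"), function(v) v > 0, "must be > 0")
  need(c("display", "refresh_hz"), function(v) v > 0, "must be > 0")
  need(c("noise", "update_rate"), function(v) v > 0, "must be > 0")
  need(c("noise", "n_steps"), function(v) v >= 1, "must be >= 1")
  need(c("noise", "mean_luminance"), function(v) v > 0 && v < 1, "must be in (0, 1)")
  need(c("noise", "contrast"), function(v) v > 0, "must be > 0")
  need(c("noise", "field_px"), function(v) length(v) == 2 && all(v >= 16),
       "must be two pixel dimensions >= 16")
  need(c("noise", "shape"), function(v) v %in% c("circular", "rectangular"),
       "must be 'circular' or 'rectangular'")
  need(c("signal", "r_deg"), function(v) v > 0, "must be > 0")
  need(c("signal", "w_deg"), function(v) v >= 0, "must be >= 0")
  need(c("signal", "tilts_deg"), function(v) length(v) >= 1, "must be non-empty")
  need(c("signal", "sigma_ladder_deg"),
       function(v) length(v) >= 1 && (length(v) == 1 || all(diff(v) > 0)),
       "must be strictly increasing")
  need(c("placement", "mode"), function(v) v %in% c("eccentricity", "position"),
       "must be 'eccentricity' or 'position'")
  need(c("placement", "values_deg"), function(v) length(v) >= 1, "must be non-empty")
  need(c("trials", "n_trials"), function(v) v >= 1, "must be >= 1")
  need(c("trials", "conditions"),
       function(v) all(v %in% c("cued", "uncued")), "must be cued/uncued")
  need("seed")

  rate <- config$noise$update_rate
  refresh <- config$display$refresh_hz
  if (!is.null(rate) && !is.null(refresh)) {
    if (abs(refresh / rate - round(refresh / rate)) > 1e-9) {
      errs <- c(errs, "display$refresh_hz must be an integer multiple of noise$update_rate")
    }
  }
  tm <- config$timing_ms
  if (is.null(tm)) {
    errs <- c(errs, "missing field: timing_ms")
  } else if (!is.null(rate)) {
    for (k in c("cue", "cue_signal_delay", "signal", "mask")) {
      v <- tm[[k]]
      if (is.null(v)) {
        errs <- c(errs, sprintf("missing field: timing_ms$%s", k))
      } else if (v > 0) {
        n <- v / 1000 * rate
        if (abs(n - round(n)) > 1e-6) {
          errs <- c(errs, sprintf(
            "timing_ms$%s = %g ms is not frame-aligned at %g Hz; nearest valid: %.4g ms (%d frames) or %.4g ms (%d frames)",
            k, v, rate, floor(n) / rate * 1000, floor(n), ceiling(n) / rate * 1000, ceiling(n)))
        }
      }
    }
    if (is.null(tm$fixation_min) || is.null(tm$fixation_max) ||
        (!is.null(tm$fixation_min) && !is.null(tm$fixation_max) &&
         tm$fixation_min > tm$fixation_max)) {
      errs <- c(errs, "timing_ms$fixation_min/fixation_max must give a valid range")
    }
  }
  if (length(errs)) {
    stop(paste0("invalid session config:\n  - ", paste(errs, collapse = "\n  - ")),
         call. = FALSE)
  }
  structure(config, class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("<session_config: %s placement, %d trials, %g Hz update, seed %s>\n",
              x$placement$mode, x$trials$n_trials, x$noise$update_rate,
              format(x$seed)))
  invisible(x)
}

#' Place the signal window for a trial
#'
#' Eccentricity mode: the window center lies at the trial's radial distance
#' from fixation, with the polar angle drawn uniformly under the trial
#' seed's placement substream. Position mode: the center sits on the
#' horizontal midline at the stated offset. Placement that would push the
#' window support (r + w) outside the noise field is an error.
#'
#' @param trial List or one-row data frame with `eccentricity` or
#'   `position` (degrees) and `seed`.
#' @param session A [session_config()].
#' @return A [window_spec()] centered for this trial.
#' @export
place_signal <- function(trial, session) {
  r <- session$signal$r_deg
  w <- session$signal$w_deg
  ppd <- session$display$ppd
  fp <- session$noise$field_px
  half_x <- fp[2] / 2 / ppd
  half_y <- fp[1] / 2 / ppd
  if (session$placement$mode == "eccentricity") {
    ecc <- trial$eccentricity
    if (ecc + r + w > min(half_x, half_y)) {
      stop(sprintf("eccentricity %g deg with window support %g deg exceeds the field half-extent %g deg",
                   ecc, r + w, min(half_x, half_y)), call. = FALSE)
    }
    theta <- with_seed(substream_seed(trial$seed, "placement"),
                       stats::runif(1, 0, 2 * pi))
    if (ecc == 0) theta <- 0
    window_spec(ecc * cos(theta), ecc * sin(theta), r, w)
  } else {
    pos <- trial$position
    if (abs(pos) + r + w > half_x || r + w > half_y) {
      stop(sprintf("position %g deg with window support %g deg exceeds the field extent",
                   pos, r + w), call. = FALSE)
    }
    window_spec(pos, 0, r, w)
  }
}

#' Build a balanced trial schedule for a session
#'
#' Crosses condition x tilt x location as evenly as the trial count allows,
#' cycles the filter-width ladder across that design, and shuffles the
#' resulting order under the schedule substream of the master seed. Each
#' trial receives its own derived seed.
#'
#' @param session A [session_config()].
#' @return Data frame with one row per trial: `trial`, `condition`, `tilt`,
#'   location column (`eccentricity` or `position`), `sigma`, `seed`.
#' @export
build_session_schedule <- function(session) {
  n <- session$trials$n_trials
  loc_name <- if (session$placement$mode == "eccentricity") "eccentricity" else "position"
  design <- expand.grid(
    condition = session$trials$conditions,
    tilt = session$signal$tilts_deg,
    loc = session$placement$values_deg,
    stringsAsFactors = FALSE
  )
  idx <- rep_len(seq_len(nrow(design)), n)
  sched <- design[idx, , drop = FALSE]
  sched$sigma <- rep_len(session$signal$sigma_ladder_deg, n)
  ord <- with_seed(substream_seed(session$seed, "schedule"), sample.int(n))
  sched <- sched[ord, , drop = FALSE]
  names(sched)[names(sched) == "loc"] <- loc_name
  sched$trial <- seq_len(n)
  sched$seed <- vapply(seq_len(n), function(i) substream_seed(session$seed, "trial", i),
                       numeric(1))
  rownames(sched) <- NULL
  sched[, c("trial", "condition", "tilt", loc_name, "sigma", "seed")]
}

#' Build one full trial
#'
#' Assembles the trial's frame sequence from the session configuration:
#' jittered fixation period (uniform draw, quantized to whole frames), cue
#' interval on cued trials, cue-signal delay, signal interval with the
#' orientation-filtered patch embedded at the placed location, and the
#' non-oriented masking period. Returns the sequence together with a
#' ground-truth record of everything a later analysis needs.
#'
#' @param trial One row of [build_session_schedule()] (list or data frame
#'   row).
#' @param session A [session_config()].
#' @return List with `sequence` (a [frame_sequence()]) and `truth` (list:
#'   trial id, condition, tilt, sigma, location, window center, event times
#'   in ms, seed).
#' @export
build_trial <- function(trial, session) {
  trial <- as.list(trial)
  rate <- session$noise$update_rate
  tm <- session$timing_ms
  fix_ms <- with_seed(substream_seed(trial$seed, "fixation"),
                      stats::runif(1, tm$fixation_min, tm$fixation_max))
  fix_f <- max(1L, as.integer(round(fix_ms / 1000 * rate)))
  cued <- identical(trial$condition, "cued")
  # uncued trials keep the identical timeline (the cue interval simply shows
  # plain background): same timing in both conditions, cue rendered at export
  cue_f <- if (tm$cue > 0) seconds_to_frames(tm$cue / 1000, rate, "cue duration") else 0L
  delay_f <- seconds_to_frames(tm$cue_signal_delay / 1000, rate, "cue-signal delay")
  sig_f <- seconds_to_frames(tm$signal / 1000, rate, "signal duration")
  mask_f <- seconds_to_frames(tm$mask / 1000, rate, "mask duration")
  total_f <- fix_f + cue_f + delay_f + sig_f + mask_f
  n_steps <- session$noise$n_steps
  n_key <- ceiling((total_f - 1L) / n_steps) + 1L

  fp <- session$noise$field_px
  mask <- session_shape_mask(session)
  stream <- make_keyframe_stream(
    n_key, fp[1], fp[2], substream_seed(trial$seed, "noise-stream"),
    mean_luminance = session$noise$mean_luminance,
    contrast = session$noise$contrast,
    n_steps = n_steps, update_rate = rate, shape_mask = mask)

  win <- place_signal(trial, session)
  onset_f <- fix_f + cue_f + delay_f
  cue <- if (cued && cue_f > 0) list(onset = fix_f / rate, duration = cue_f / rate) else NULL
  seq <- build_dynamic_stimulus(
    stream,
    signal_spec = orientation_filter_spec(trial$tilt, trial$sigma),
    window = win,
    signal_onset = onset_f / rate,
    signal_duration = sig_f / rate,
    ppd = session$display$ppd,
    cue = cue)
  seq$frames <- seq$frames[seq_len(total_f)]
  seq$repeat_factor <- as.integer(round(session$display$refresh_hz / rate))
  seq$cue_window <- if (cued) win else NULL

  loc <- if (session$placement$mode == "eccentricity") {
    list(eccentricity = trial$eccentricity)
  } else {
    list(position = trial$position)
  }
  truth <- c(list(
    trial = trial$trial, condition = trial$condition,
    tilt = trial$tilt, sigma = trial$sigma,
    center_x = win$center_x, center_y = win$center_y,
    signal_on_ms = onset_f / rate * 1000,
    signal_off_ms = (onset_f + sig_f) / rate * 1000,
    seed = trial$seed), loc)
  list(sequence = seq, truth = truth)
}

# Field aperture implied by the session's noise geometry (NULL if the
# noise field fills its pixel rectangle).
session_shape_mask <- function(session) {
  fp <- session$noise$field_px
  ppd <- session$display$ppd
  if (identical(session$noise$shape, "circular") &&
      !is.null(session$noise$field_radius_deg)) {
    field_shape_mask(fp[1], fp[2], ppd, "circular",
                     radius = session$noise$field_radius_deg,
                     ramp = session$noise$field_ramp_deg %||% 0)
  } else if (identical(session$noise$shape, "rectangular") &&
             !is.null(session$noise$field_height_deg)) {
    field_shape_mask(fp[1], fp[2], ppd, "rectangular",
                     rect_height = session$noise$field_height_deg,
                     rect_width = session$noise$field_width_deg)
  } else {
    NULL
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Circular placeholder-frame overlay
#'
#' Ring outlines (e.g. the five task-irrelevant circles on the horizontal
#' midline of the rectangular-field experiment) drawn onto every frame at
#' export/display time. Pixels whose distance from a ring center differs
#' from `radius` by more than half the stroke width are untouched.
#'
#' @param positions Horizontal ring-center offsets in degrees relative to
#'   field center.
#' @param radius Ring radius in degrees.
#' @param stroke Stroke width in degrees.
#' @param value Luminance painted on the stroke (dark outlines by default).
#' @return An object of class `frames_overlay`.
#' @export
build_frames_overlay <- function(positions, radius = 1.0, stroke = 0.1, value = 0.05) {
  stopifnot(radius > 0, stroke > 0)
  structure(list(positions = positions, radius = radius, stroke = stroke,
                 value = value),
            class = "frames_overlay")
}

#' Rasterize and apply a frames overlay
#'
#' @param pixels Image matrix.
#' @param overlay A [build_frames_overlay()] object.
#' @param ppd Pixels per degree.
#' @return Image matrix with ring strokes painted.
#' @export
apply_frames_overlay <- function(pixels, overlay, ppd) {
  h <- nrow(pixels); w <- ncol(pixels)
  for (p in overlay$positions) {
    d <- window_distance_map(h, w, window_spec(p, 0, overlay$radius, 0), ppd)
    if (min(d) > overlay$radius) {
      stop(sprintf("frame at %g deg does not fit in the field", p), call. = FALSE)
    }
    pixels[abs(d - overlay$radius) <= overlay$stroke / 2] <- overlay$value
  }
  pixels
}

# Pixel mask of the strokes only (diagnostics / tests).
overlay_stroke_mask <- function(height, width, overlay, ppd) {
  m <- matrix(FALSE, height, width)
  for (p in overlay$positions) {
    d <- window_distance_map(height, width, window_spec(p, 0, overlay$radius, 0), ppd)
    m <- m | (abs(d - overlay$radius) <= overlay$stroke / 2)
  }
  m
}
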