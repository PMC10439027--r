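#' Synthetic 2AFC observer model
#'
#' Phenomenological stand-in for a human observer: accuracy follows a
#' cumulative-Gaussian psychometric function of the orientation filter
#' width (guess rate 0.5), with an optional lapse rate and an attention
#' gain that multiplies the effective signal strength at cued locations.
#' Uncued signals away from fixation are discriminated at chance — the
#' behavioral signature that the embedded signal does not capture attention
#' on its own. The model emulates response structure only; it does not
#' model acuity falloff or any other property of human peripheral vision.
#'
#' @param mu_true True filter-width threshold in degrees (accuracy 0.75 at
#'   `sigma = mu_true` when cued, lapse 0, gain 1).
#' @param slope_true Psychometric spread in degrees, > 0.
#' @param lapse Lapse rate in `[0, 0.1]`.
#' @param attention_gain Multiplier on effective signal strength when cued
#'   (effective filter width is `sigma / attention_gain`).
#' @param seed RNG seed for response simulation.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(mu_true = 50, slope_true = 10, lapse = 0,
                           attention_gain = 1, seed = 1) {
  if (slope_true <= 0) stop("`slope_true` must be > 0", call. = FALSE)
  if (lapse < 0 || lapse > 0.1) stop("`lapse` must be in [0, 0.1]", call. = FALSE)
  if (attention_gain <= 0) stop("`attention_gain` must be > 0", call. = FALSE)
  structure(list(mu_true = mu_true, slope_true = slope_true, lapse = lapse,
                 attention_gain = attention_gain, seed = seed),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf("<observer_model mu = %g deg, slope = %g deg, lapse = %g, gain = %g>\n",
              x$mu_true, x$slope_true, x$lapse, x$attention_gain))
  invisible(x)
}

# P(correct) for a filter width under the model (decreasing abscissa).
observer_p_correct <- function(model, sigma) {
  0.5 + (0.5 - model$lapse) *
    stats::pnorm(-(sigma - model$mu_true) / model$slope_true)
}

#' Simulate 2AFC responses for a trial schedule
#'
#' For each trial: cued trials (and uncued trials at fixation, eccentricity
#' 0) respond with accuracy `Psi(sigma_eff)` from the observer's
#' psychometric model, where `sigma_eff = sigma / attention_gain` on cued
#' trials; uncued trials away from fixation respond at chance (0.5).
#' Responses are Bernoulli draws under the model's response substream.
#'
#' @param trials Data frame with columns `condition` ("cued"/"uncued") and
#'   `sigma`; optional `eccentricity` (degrees, default 0) or `position`.
#' @param model An [observer_model()].
#' @param observer_id Label written into the `observer` column.
#' @return The `trials` data frame with added columns `observer`,
#'   `p_correct` and `correct`.
#' @export
simulate_responses <- function(trials, model, observer_id = "sim1") {
  stopifnot(is.data.frame(trials),
            all(c("condition", "sigma") %in% names(trials)))
  ecc <- if ("eccentricity" %in% names(trials)) abs(trials$eccentricity)
    else if ("position" %in% names(trials)) abs(trials$position)
    else rep(0, nrow(trials))
  cued <- trials$condition == "cued"
  sigma_eff <- ifelse(cued, trials$sigma / model$attention_gain, trials$sigma)
  p <- ifelse(cued | ecc == 0,
              observer_p_correct_eff(model, sigma_eff),
              0.5)
  correct <- with_seed(substream_seed(model$seed, "responses"),
                       stats::rbinom(nrow(trials), 1, p))
  out <- trials
  out$observer <- observer_id
  out$p_correct <- p
  out$correct <- correct
  out
}

observer_p_correct_eff <- function(model, sigma_eff) {
  0.5 + (0.5 - model$lapse) *
    stats::pnorm(-(sigma_eff - model$mu_true) / model$slope_true)
}

#' Render a minimal probe trial for image-computable decoding
#'
#' Small dynamic movie with one embedded signal interval: a seeded keyframe
#' stream, hybrid stepping, and the orientation signal filtered into each
#' signal frame at the given location. A compact harness for decoder
#' studies where the full session timing is irrelevant.
#'
#' @param sigma Orientation filter width in degrees.
#' @param tilt Signal orientation in degrees (e.g. +40 / -40).
#' @param center_x,center_y Signal location in degrees from field center.
#' @param geometry List with `height`, `width` (pixels) and `ppd`.
#' @param r,w Window plateau radius and ramp in degrees.
#' @param seed Trial seed.
#' @param n_keyframes,n_steps Stream shape (defaults give a 4-frame movie
#'   whose last three frames carry the signal).
#' @param signal_frames Number of signal frames.
#' @param update_rate Hz.
#' @param mean_luminance,contrast Field statistics.
#' @return A [frame_sequence()] with signal events annotated.
#' @export
build_probe_sequence <- function(sigma, tilt, center_x = 0, center_y = 0,
                                 geometry = list(height = 256, width = 256, ppd = 8),
                                 r = 1.75, w = 0.875, seed = 1,
                                 n_keyframes = 2, n_steps = 3,
                                 signal_frames = 3, update_rate = 60,
                                 mean_luminance = 0.5, contrast = 0.2) {
  stream <- make_keyframe_stream(
    n_keyframes, geometry$height, geometry$width, seed,
    mean_luminance = mean_luminance, contrast = contrast,
    n_steps = n_steps, update_rate = update_rate)
  build_dynamic_stimulus(
    stream,
    signal_spec = orientation_filter_spec(tilt, sigma),
    window = window_spec(center_x, center_y, r, w),
    signal_onset = 1 / update_rate,
    signal_duration = signal_frames / update_rate,
    ppd = geometry$ppd)
}

#' Decode the embedded tilt from rendered frames
#'
#' Fixed orientation-energy model (no training): over the signal frames
#' identified from the sequence's events, the mean-subtracted frame is
#' windowed by the analysis window's raised cosine, and the decision
#' statistic is the spectral energy within `half_width` degrees of the
#' clockwise band (+|tilt|) minus the counterclockwise band (-|tilt|),
#' averaged across signal frames. The decoded tilt is the sign of the
#' statistic.
#'
#' @param sequence A [frame_sequence()] with signal events.
#' @param truth Ground-truth record with a `tilt` field (signed degrees).
#' @param analysis_window [window_spec()] centered on the analysed
#'   location.
#' @param ppd Pixels per degree.
#' @param half_width Band half-width in degrees (fixed a priori at 15).
#' @return List: `statistic`, `decoded_tilt`, `correct`, `per_frame`.
#' @export
decode_tilt <- function(sequence, truth, analysis_window, ppd, half_width = 15) {
  rng <- signal_frame_range(sequence)
  if (is.null(rng)) stop("sequence has no signal frames to decode", call. = FALSE)
  mag <- abs(truth$tilt)
  dims <- dim(sequence$frames[[1]])
  wmap <- raised_cosine_window(dims[1], dims[2], analysis_window, ppd)
  per_frame <- vapply(rng[1]:rng[2], function(k) {
    fr <- sequence$frames[[k]]
    patch <- wmap * (fr - mean(fr))
    orientation_band_energy(patch, mag, half_width) -
      orientation_band_energy(patch, -mag, half_width)
  }, numeric(1))
  statistic <- mean(per_frame)
  decoded <- if (statistic >= 0) mag else -mag
  list(statistic = statistic, decoded_tilt = decoded,
       correct = decoded == truth$tilt, per_frame = per_frame)
}

#' Decoder accuracy study over filter widths
#'
#' Renders `n_trials` probe trials per filter width (tilt +/-
#' `tilt_magnitude` balanced, fresh seeds per trial), decodes each with the
#' orientation-energy model, and tabulates accuracy. `window_offset`
#' displaces the analysis window from the true signal location (degrees),
#' for location-mismatch controls.
#'
#' @param sigmas Filter widths in degrees.
#' @param n_trials Trials per width.
#' @param geometry List with `height`, `width`, `ppd`.
#' @param r,w Signal window geometry in degrees.
#' @param tilt_magnitude Unsigned tilt in degrees.
#' @param center_x,center_y Signal location in degrees.
#' @param window_offset Length-2 displacement of the analysis window
#'   (degrees).
#' @param seed Master seed.
#' @param half_width Decoder band half-width.
#' @return Data frame: `sigma`, `accuracy`, `n`, `mean_statistic`.
#' @export
run_decoder_study <- function(sigmas, n_trials = 200,
                              geometry = list(height = 256, width = 256, ppd = 8),
                              r = 1.75, w = 0.875, tilt_magnitude = 40,
                              center_x = 0, center_y = 0,
                              window_offset = c(0, 0), seed = 1,
                              half_width = 15) {
  analysis <- window_spec(center_x + window_offset[1], center_y + window_offset[2],
                          r, w)
  rows <- lapply(seq_along(sigmas), function(si) {
    sg <- sigmas[si]
    res <- vapply(seq_len(n_trials), function(t) {
      tilt <- if (t %% 2 == 0) tilt_magnitude else -tilt_magnitude
      sq <- build_probe_sequence(
        sg, tilt, center_x, center_y, geometry, r = r, w = w,
        seed = substream_seed(seed, sprintf("decoder-%g", sg), t))
      dec <- decode_tilt(sq, list(tilt = tilt), analysis, geometry$ppd,
                         half_width = half_width)
      c(correct = as.numeric(dec$correct), stat = dec$statistic)
    }, numeric(2))
    data.frame(sigma = sg, accuracy = mean(res["correct", ]),
               n = n_trials, mean_statistic = mean(res["stat", ]))
  })
  do.call(rbind, rows)
}

#' Closed-loop recovery run: generate, simulate, fit
#'
#' End-to-end harness without imaging: builds the session's trial schedule,
#' simulates the synthetic observer's responses, and fits a
#' cumulative-Gaussian psychometric function per condition (cued trials
#' pooled across locations; uncued fitted at fixation only, where the model
#' is above chance). Reports the recovered Th75 against the model's ground
#' truth.
#'
#' @param session A [session_config()].
#' @param model An [observer_model()].
#' @return List: `responses`, `fits` (per condition), `recovery` (data
#'   frame: condition, th75_true, th75_recovered, error).
#' @export
run_closed_loop <- function(session, model) {
  sched <- build_session_schedule(session)
  responses <- simulate_responses(sched, model)
  conds <- unique(responses$condition)
  fits <- list()
  rec <- list()
  for (cond in conds) {
    sub <- responses[responses$condition == cond, , drop = FALSE]
    if (cond == "uncued" && "eccentricity" %in% names(sub)) {
      sub <- sub[sub$eccentricity == 0, , drop = FALSE]
    }
    if (nrow(sub) < 10 || length(unique(sub$sigma)) < 2) next
    fit <- fit_cumulative_gaussian(sub, abscissa = "sigma")
    fits[[cond]] <- fit
    truth <- if (cond == "cued") model$mu_true * model$attention_gain else model$mu_true
    rec[[cond]] <- data.frame(
      condition = cond, th75_true = truth,
      th75_recovered = fit$th75, error = fit$th75 - truth,
      converged = fit$converged)
  }
  list(responses = responses, fits = fits, recovery = do.call(rbind, rec))
}
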