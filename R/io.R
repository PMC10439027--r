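#' Load and validate a session configuration file
#'
#' Reads a YAML session description, checks the schema version and every
#' field constraint (frame alignment of all timings, ladder monotonicity,
#' geometry), and returns a validated [session_config()]. Validation
#' collects all offending fields before failing, so a broken file reports
#' everything at once. Shipped fixtures: `exp1a.yaml` (circular field, four
#' eccentricities, cued/uncued) and `exp2.yaml` (rectangular strip, nine
#' horizontal positions), under `system.file("extdata", package =
#' "pinkstim")`.
#'
#' @param path Path to a YAML config.
#' @return A `session_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  session_config(yaml::read_yaml(path))
}

#' Quantize luminance to a bit depth
#'
#' Clips to the normalized `[0, 1]` range, then rounds half-to-even onto
#' the `2^bits - 1` grid. This is the exact value an exported image file
#' stores, so a write/read round trip reproduces it bit-identically.
#'
#' @param x Numeric matrix or vector of normalized luminances.
#' @param bits Bit depth (8 or 16).
#' @return Quantized values, still in `[0, 1]`.
#' @export
quantize_luminance <- function(x, bits = 16) {
  stopifnot(bits %in% c(8, 16))
  levels <- 2^bits - 1
  round(pmin(pmax(x, 0), 1) * levels) / levels
}

#' Render the color cue overlay onto a grayscale frame
#'
#' The exogenous cue is a pink circular outline of the signal window's
#' dimensions, drawn at export time (the noise itself stays grayscale).
#' Returns an RGB array with the ring stroke painted in the cue color.
#'
#' @param pixels Grayscale frame matrix (normalized luminance).
#' @param window [window_spec()] at the cue location.
#' @param ppd Pixels per degree.
#' @param rgb Cue color as normalized RGB (default pink, 204/0/102).
#' @param stroke Ring stroke width in degrees.
#' @return `height x width x 3` array.
#' @export
render_cue_overlay <- function(pixels, window, ppd,
                               rgb = c(204, 0, 102) / 255, stroke = 0.15) {
  h <- nrow(pixels); w <- ncol(pixels)
  d <- window_distance_map(h, w, window, ppd)
  ring <- abs(d - (window$r + window$w)) <= stroke / 2
  out <- array(rep(pixels, 3), dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[ring] <- rgb[ch]
    out[, , ch] <- plane
  }
  out
}

#' Write a frame sequence to numbered image files with an event sidecar
#'
#' Exports every frame as a zero-padded numbered grayscale image plus an
#' `events.json` sidecar (array of `{frame_index, t_ms, labels}` objects).
#' Two formats are supported: 8-bit PNG and lossless 16-bit TIFF (default;
#' its quantization step of 1/65535 sits far below the statistics
#' tolerances used elsewhere). Pixels are clipped and rounded half-to-even
#' to the bit depth ([quantize_luminance()]); a read-back reproduces the
#' written values exactly. The sequence's field aperture (shape mask), if
#' any, is applied here. On cued sequences, `render_cue = TRUE` writes the
#' cue frames as RGB with the pink ring overlay.
#'
#' @param sequence A [frame_sequence()].
#' @param dir Output directory (created if missing).
#' @param bit_depth 8 (PNG) or 16 (TIFF).
#' @param stem File-name stem.
#' @param render_cue Paint the cue overlay on cue frames (requires the
#'   sequence to carry `cue_window`).
#' @return Invisible list: `files`, `events_path`.
#' @export
write_frames <- function(sequence, dir, bit_depth = 16, stem = "frame",
                         render_cue = FALSE) {
  stopifnot(inherits(sequence, "frame_sequence"), bit_depth %in% c(8, 16))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (bit_depth == 8) "png" else "tif"
  n <- length(sequence$frames)
  width_digits <- max(4L, nchar(n))
  cue_frames <- integer()
  if (render_cue && !is.null(sequence$cue_window)) {
    ev <- sequence$events
    on <- ev$frame[ev$label == "cue_on"]
    off <- ev$frame[ev$label == "cue_off"]
    if (length(on) && length(off)) cue_frames <- on[1]:(off[1] - 1L)
  }
  files <- character(n)
  for (k in seq_len(n)) {
    px <- sequence$frames[[k]]
    if (!is.null(sequence$shape_mask)) {
      px <- apply_shape_mask(px, sequence$shape_mask, sequence$mean_luminance)
    }
    img <- quantize_luminance(px, bit_depth)
    if (k %in% cue_frames) {
      img <- render_cue_overlay(img, sequence$cue_window,
                                attr(sequence, "ppd") %||% 1)
      img <- quantize_luminance(img, bit_depth)
    }
    f <- file.path(dir, sprintf("%s-%0*d.%s", stem, width_digits, k, ext))
    ok <- tryCatch({
      if (bit_depth == 8) png::writePNG(img, f)
      else tiff::writeTIFF(img, f, bits.per.sample = 16L)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop(sprintf("failed writing frame %d to %s: %s", k, f, conditionMessage(ok)),
           call. = FALSE)
    }
    files[k] <- f
  }
  ev <- sequence$events
  sidecar <- lapply(sort(unique(c(ev$frame))), function(fr) {
    list(frame_index = fr,
         t_ms = (fr - 1L) / sequence$update_rate * 1000,
         labels = as.list(ev$label[ev$frame == fr]))
  })
  events_path <- file.path(dir, "events.json")
  jsonlite::write_json(sidecar, events_path, auto_unbox = TRUE, digits = NA)
  invisible(list(files = files, events_path = events_path))
}

#' Read back an exported frame
#'
#' @param path A file written by [write_frames()].
#' @return Grayscale matrix (or RGB array for cue frames).
#' @export
read_frame <- function(path) {
  if (grepl("\\.png$", path)) png::readPNG(path) else tiff::readTIFF(path)
}

#' Export an image matrix as grayscale PNG
#'
#' Documentation/diagnostic export (e.g. orientation-filter weight maps or
#' single noise fields) at 8-bit depth after clip-and-round quantization.
#'
#' @param x Matrix with values in (or clipped to) `[0, 1]`.
#' @param path Output path.
#' @return Invisible `path`.
#' @export
write_image_png <- function(x, path) {
  png::writePNG(quantize_luminance(x, 8), path)
  invisible(path)
}

#' Build a reproducibility manifest for a run
#'
#' Records everything needed to regenerate a run's outputs bit-exactly:
#' a hash of the configuration, the package version, the master seed, the
#' named per-stage substream seeds, the output file list and a timestamp.
#' The hash covers (config, seed), so it changes iff either changes.
#'
#' @param config The session config (or any serializable configuration).
#' @param seed Master seed.
#' @param files Character vector of output files.
#' @param stages Stage names whose substream seeds to record.
#' @return An object of class `run_manifest` (a list).
#' @export
run_manifest <- function(config, seed, files = character(),
                         stages = c("noise", "placement", "responses", "permutation")) {
  cfg <- unclass(config)
  stage_seeds <- stats::setNames(
    lapply(stages, function(s) substream_seed(seed, s)), stages)
  structure(
    list(config_hash = rlang::hash(list(cfg, as.integer(seed))),
         package_version = as.character(utils::packageVersion("pinkstim")),
         master_seed = as.integer(seed),
         stage_seeds = stage_seeds,
         files = files,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return Invisible `path`.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
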