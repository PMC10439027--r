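test_that("hybrid frames mix keyframes with monotone weights", {
  A <- generate_pink_noise(64, 64, seed = 41)
  B <- generate_pink_noise(64, 64, seed = 42)
  hybrids <- interpolate_keyframes(A, B, 4)
  expect_length(hybrids, 4)
  # recover the implied mixing weight of B by per-pixel regression
  wb <- vapply(hybrids, function(h) {
    cf <- stats::coef(stats::lm(c(h) ~ c(A$pixels) + c(B$pixels)))
    unname(cf[3] / (cf[2] + cf[3]))
  }, numeric(1))
  expect_true(all(diff(wb) > 0))
  # the middle hybrid of an even sequence is the symmetric AB mix
  expect_equal(wb[2], 0.5, tolerance = 1e-9)
  expect_equal(wb[4], 1, tolerance = 1e-9)
  # fixed point: A == B leaves every hybrid at A
  same <- interpolate_keyframes(A, A, 4)
  for (h in same) expect_equal(h, A$pixels, tolerance = 1e-9)
  expect_error(interpolate_keyframes(A, B, 0), "n_steps")
})

test_that("statistics adjustment restores contrast lost to mixing", {
  A <- generate_pink_noise(128, 128, seed = 43)
  B <- generate_pink_noise(128, 128, seed = 44)
  raw_mix <- 0.5 * A$pixels + 0.5 * B$pixels
  # independent fields: the midpoint mix loses ~1/sqrt(2) of RMS contrast
  expect_equal(rms_contrast(raw_mix), 0.2 / sqrt(2), tolerance = 0.05)
  adj <- adjust_image_statistics(raw_mix, 0.5, 0.2)
  expect_equal(mean(adj), 0.5, tolerance = 1e-9)
  expect_equal(rms_contrast(adj), 0.2, tolerance = 1e-9)
  # idempotence
  expect_equal(adjust_image_statistics(adj, 0.5, 0.2), adj, tolerance = 1e-12)
  expect_equal(adjust_image_statistics(A$pixels, 0.5, 0.2), A$pixels,
               tolerance = 1e-12)
  expect_error(adjust_image_statistics(matrix(1, 8, 8), 0.5, 0.2), "constant")
})

test_that("timings must align to whole frames, with nearest alternatives reported", {
  err <- tryCatch(pinkstim:::seconds_to_frames(0.075, 60, "cue duration"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "75 ms is not a whole number of frames")
  expect_match(err, "4 frames")
  expect_match(err, "5 frames")
  expect_equal(pinkstim:::seconds_to_frames(0.05, 60), 3L)
})

test_that("dynamic stimulus embeds the signal for exactly the requested frames", {
  st <- make_keyframe_stream(6, 64, 64, seed = 45, n_steps = 4, update_rate = 60)
  spec <- orientation_filter_spec(40, 30)
  win <- window_spec(0, 0, 1.75, 0.875)
  sq <- build_dynamic_stimulus(st, spec, win, signal_onset = 10 / 60,
                               signal_duration = 0.05, ppd = 8)
  ev <- sq$events
  expect_equal(ev$frame[ev$label == "signal_on"], 11)
  expect_equal(ev$frame[ev$label == "signal_off"], 14) # 50 ms at 60 Hz = 3 frames
  expect_equal(ev$frame[ev$label == "mask_on"], 14)
  # frames before signal onset are bit-identical to a signal-free build
  plain <- build_dynamic_stimulus(st)
  for (k in 1:10) expect_identical(sq$frames[[k]], plain$frames[[k]])
  for (k in 15:length(sq$frames)) expect_identical(sq$frames[[k]], plain$frames[[k]])
  # signal frames differ from background inside the window only
  W <- raised_cosine_window(64, 64, win, 8)
  diff12 <- abs(sq$frames[[12]] - plain$frames[[12]])
  expect_gt(max(diff12[W > 0]), 0)
  # every frame keeps the target statistics
  for (fr in sq$frames) {
    expect_equal(mean(fr), 0.5, tolerance = 1e-6)
    expect_equal(rms_contrast(fr), 0.2, tolerance = 1e-6)
  }
  # determinism of the full pipeline
  st2 <- make_keyframe_stream(6, 64, 64, seed = 45, n_steps = 4, update_rate = 60)
  sq2 <- build_dynamic_stimulus(st2, spec, win, signal_onset = 10 / 60,
                                signal_duration = 0.05, ppd = 8)
  expect_identical(sq$frames, sq2$frames)
  # signal interval outside the movie is an error
  expect_error(
    build_dynamic_stimulus(st, spec, win, signal_onset = 100, signal_duration = 0.05,
                           ppd = 8),
    "outside the .*movie")
})

test_that("signal onset is concealed by the ongoing full-field changes", {
  st <- make_keyframe_stream(10, 128, 128, seed = 46, n_steps = 4, update_rate = 60)
  sq <- build_dynamic_stimulus(st, orientation_filter_spec(-40, 30),
                               window_spec(2, 1, 1.75, 0.875),
                               signal_onset = 20 / 60, signal_duration = 0.05,
                               ppd = 8)
  cr <- concealment_ratio(sq)
  expect_gt(cr$ratio, 0.5)
  expect_lt(cr$ratio, 2)
})

test_that("stream constructors validate their inputs", {
  A <- generate_pink_noise(32, 32, seed = 47)
  expect_error(keyframe_stream(list(A), 4, 60), "at least 2")
  B <- generate_pink_noise(32, 32, seed = 48, mean_luminance = 0.6)
  expect_error(keyframe_stream(list(A, B), 4, 60), "share target mean")
  C <- generate_pink_noise(64, 64, seed = 49)
  expect_error(keyframe_stream(list(A, C), 4, 60), "share dimensions")
})
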