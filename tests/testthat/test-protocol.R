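test_that("shipped configs load with the published parameter ladders", {
  cfg1 <- load_config(system.file("extdata", "exp1a.yaml", package = "pinkstim"))
  expect_equal(cfg1$placement$values_deg, c(0, 3.5, 7, 10.5))
  expect_equal(cfg1$signal$sigma_ladder_deg, seq(30, 70, 5))
  expect_equal(cfg1$signal$r_deg, 1.75)
  cfg2 <- load_config(system.file("extdata", "exp2.yaml", package = "pinkstim"))
  expect_equal(cfg2$placement$values_deg, c(-8, -6, -4, -2, 0, 2, 4, 6, 8))
  expect_equal(cfg2$signal$r_deg, 1.0)
})

test_that("misaligned timings are rejected naming the nearest frame counts", {
  cfg <- unclass(tiny_session())
  cfg$timing_ms$cue <- 75 # 4.5 frames at 60 Hz
  err <- tryCatch(session_config(cfg), error = function(e) conditionMessage(e))
  expect_match(err, "75 ms is not frame-aligned")
  expect_match(err, "4 frames")
  expect_match(err, "5 frames")
  # validation reports every offending field at once
  cfg$signal$sigma_ladder_deg <- c(50, 30)
  cfg$placement$mode <- "somewhere"
  err2 <- tryCatch(session_config(cfg), error = function(e) conditionMessage(e))
  expect_match(err2, "sigma_ladder_deg")
  expect_match(err2, "placement\\$mode")
  expect_match(err2, "frame-aligned")
})

test_that("signal placement respects eccentricity exactly with uniform polar angle", {
  sess <- tiny_session()
  centers <- t(vapply(1:1000, function(i) {
    w <- place_signal(list(eccentricity = 7, seed = i), sess)
    c(w$center_x, w$center_y)
  }, numeric(2)))
  rad <- sqrt(rowSums(centers^2))
  expect_true(all(abs(rad - 7) < 1e-9))
  ang <- atan2(centers[, 2], centers[, 1])
  counts <- table(cut(ang, seq(-pi, pi, length.out = 9)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  # eccentricity zero is fixation itself
  w0 <- place_signal(list(eccentricity = 0, seed = 1), sess)
  expect_equal(c(w0$center_x, w0$center_y), c(0, 0))
  # position mode converts degrees to the stated pixel offset
  cfg2 <- load_config(system.file("extdata", "exp2.yaml", package = "pinkstim"))
  wp <- place_signal(list(position = 4, seed = 2), cfg2)
  expect_equal(wp$center_x * cfg2$display$ppd, 4 * 26.8)
  expect_equal(wp$center_y, 0)
  # impossible placements error
  expect_error(place_signal(list(eccentricity = 20, seed = 1), sess),
               "exceeds the field")
})

test_that("trial schedules are balanced and reproducible", {
  sess <- tiny_session(n_trials = 144, seed = 7)
  sched <- build_session_schedule(sess)
  expect_equal(nrow(sched), 144)
  expect_equal(unname(table(sched$condition)), c(72, 72), ignore_attr = TRUE)
  expect_equal(unname(table(sched$tilt)), c(72, 72), ignore_attr = TRUE)
  expect_true(all(table(sched$eccentricity) == 36))
  expect_equal(max(table(sched$sigma)), 16)
  expect_identical(sched, build_session_schedule(tiny_session(144, seed = 7)))
  expect_false(identical(sched$trial[order(sched$seed)],
                         build_session_schedule(tiny_session(144, seed = 8))$trial[
                           order(build_session_schedule(tiny_session(144, seed = 8))$seed)]))
})

test_that("built trials carry the scheduled ground truth and timing", {
  sess <- tiny_session(seed = 3)
  sched <- build_session_schedule(sess)
  cued_row <- sched[sched$condition == "cued", ][1, ]
  tr <- build_trial(cued_row, sess)
  expect_s3_class(tr$sequence, "frame_sequence")
  expect_identical(tr$truth$tilt, cued_row$tilt)
  expect_identical(tr$truth$sigma, cued_row$sigma)
  expect_identical(tr$truth$condition, "cued")
  ev <- tr$sequence$events
  expect_true(all(c("cue_on", "cue_off", "signal_on", "signal_off") %in% ev$label))
  # cue (4 frames) ends 100 ms (6 frames) before signal onset
  expect_equal(ev$frame[ev$label == "signal_on"] - ev$frame[ev$label == "cue_off"], 6)
  expect_equal(ev$frame[ev$label == "cue_off"] - ev$frame[ev$label == "cue_on"], 4)
  # signal lasts 3 frames at 60 Hz
  expect_equal(ev$frame[ev$label == "signal_off"] - ev$frame[ev$label == "signal_on"], 3)
  expect_equal(tr$sequence$repeat_factor, 2L)
  # an uncued twin with the same seed shares all frames outside the cue window
  uncued_row <- cued_row
  uncued_row$condition <- "uncued"
  tru <- build_trial(uncued_row, sess)
  expect_identical(tr$sequence$frames, tru$sequence$frames)
  expect_false("cue_on" %in% tru$sequence$events$label)
})

test_that("a full session block builds with every frame on target", {
  sess <- tiny_session(n_trials = 30, seed = 9)
  sched <- build_session_schedule(sess)
  for (i in seq_len(nrow(sched))) {
    tr <- build_trial(sched[i, ], sess)
    mx <- vapply(tr$sequence$frames, mean, numeric(1))
    expect_true(all(abs(mx - 0.5) < 1e-6))
    ev <- tr$sequence$events
    expect_true(all(ev$frame >= 1 & ev$frame <= length(tr$sequence$frames) + 1))
    expect_lt(ev$frame[ev$label == "signal_on"], ev$frame[ev$label == "signal_off"])
  }
})

test_that("placeholder ring overlays touch only their strokes", {
  ov <- build_frames_overlay(c(-8, -4, 0, 4, 8), radius = 1.0, stroke = 0.15,
                             value = 0.05)
  ppd <- 26.8
  px <- generate_pink_noise(128, 544, seed = 51)$pixels
  out <- apply_frames_overlay(px, ov, ppd)
  strokes <- pinkstim:::overlay_stroke_mask(128, 544, ov, ppd)
  expect_identical(out[!strokes], px[!strokes])
  expect_true(all(out[strokes] == 0.05))
  # rasterized stroke size matches the ring circumference within discretization
  one <- pinkstim:::overlay_stroke_mask(128, 544, build_frames_overlay(0, 1, 0.15), ppd)
  expected <- 2 * pi * 1 * ppd * (0.15 * ppd)
  expect_lt(abs(sum(one) - expected) / expected, 0.35)
})
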