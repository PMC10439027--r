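# Shared fixtures: everything is generated in code at test time.

# Reduced-geometry session config (same schema as the shipped fixtures but
# small enough that whole trials build in milliseconds).
tiny_session <- function(n_trials = 8, seed = 1, conditions = c("cued", "uncued")) {
  session_config(list(
    schema_version = 1,
    display = list(width_px = 64, height_px = 64, ppd = 2, refresh_hz = 120),
    noise = list(update_rate = 60, n_steps = 4, mean_luminance = 0.5,
                 contrast = 0.2, field_px = c(64, 64), shape = "circular",
                 field_radius_deg = 14, field_ramp_deg = 2),
    signal = list(r_deg = 1.75, w_deg = 0.875, tilts_deg = c(-40, 40),
                  sigma_ladder_deg = seq(30, 70, 5)),
    placement = list(mode = "eccentricity", values_deg = c(0, 3.5, 7, 10.5)),
    timing_ms = list(fixation_min = 100, fixation_max = 200,
                     cue = 200 / 3, cue_signal_delay = 100,
                     signal = 50, mask = 100),
    trials = list(n_trials = n_trials, conditions = conditions),
    seed = seed
  ))
}

# Periodic left-right flip consistent with DFT index negation (x -> -x mod N).
flip_lr_periodic <- function(m) {
  n <- ncol(m)
  m[, c(1L, n:2L), drop = FALSE]
}

# Periodic roll of a matrix by (dr, dc) pixels.
roll_matrix <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1L - dr) %% h) + 1L, ((seq_len(w) - 1L - dc) %% w) + 1L]
}

# Simulated paired-observer accuracy table for permutation tests.
null_pair_table <- function(n_obs = 12, n_per = 10, seed = 1, mean = 0.7, sd = 0.1) {
  tab <- data.frame(
    observer = rep(seq_len(n_obs), each = 2 * n_per),
    condition = rep(rep(c("a", "b"), each = n_per), n_obs)
  )
  tab$correct <- with_seed(seed, stats::rnorm(nrow(tab), mean, sd))
  tab
}

rms_contrast <- function(x) {
  sqrt(mean((x - mean(x))^2)) / mean(x)
}
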