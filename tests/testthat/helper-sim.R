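# Simulation helpers for tests: parameter sets with all stochastic
# components disabled, and small cohorts.

noiseless_params <- function(...) {
  args <- list(
    n_per_age = c("5mo" = 1L, "10mo" = 1L),
    random_intercept_sd_mm = 0, tonic_jitter_sd_mm = 0,
    drift_slope_sd_mm_s = 0, gain_jitter_sd_mm = 0,
    dilation_intercept_sd_mm = 0, latency_infant_sdlog = 0,
    p_latency_low = 0, p_latency_high = 0,
    blink_rate_hz = 0, offscreen_rate = 0, attrition_sdlog = 0,
    pupil_noise_sd_mm = 0, gaze_noise_sd_deg = 0)
  do.call(sim_params, utils::modifyList(args, list(...)))
}

# single-trial series builder for gaze/pupil unit tests
flat_series <- function(n = 120, fs = 600, x = 0, y = 0, p = 4) {
  t <- (seq_len(n) - 1L) / fs
  data.frame(t = t, lx = rep(x, n), ly = rep(y, n),
             rx = rep(x, n), ry = rep(y, n),
             lp = rep(p, n), rp = rep(p, n))
}
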