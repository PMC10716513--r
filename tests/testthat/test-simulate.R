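test_that("simulated trials conserve the sample grid and event layout", {
  p <- noiseless_params()
  co <- simulate_cohort(p, seed = 3)
  ns <- co$samples[, .N, by = c("id", "trial")]
  m <- merge(ns, co$events[, c("id", "trial_index", "trial_end_s")],
             by.x = c("id", "trial"), by.y = c("id", "trial_index"))
  expect_true(all(abs(m$N - m$trial_end_s * p$fs) <= 1))
  # markers: sound < visual = sound + isi; offset = visual + 3 s
  ev <- co$events
  expect_true(all(ev$visual_onset_s - ev$sound_onset_s - ev$isi_s < 1e-12))
  expect_equal(ev$visual_offset_s, ev$visual_onset_s + 3)
  # strictly increasing time within trial
  expect_silent(pupilpop:::stop_if_nonmonotone_(
    co$samples$t, data.table::rleid(co$samples$id, co$samples$trial)))
})

test_that("cohort simulation is deterministic given the seed", {
  p <- noiseless_params(blink_rate_hz = 0.2, pupil_noise_sd_mm = 0.05,
                        gaze_noise_sd_deg = 0.5)
  a <- simulate_cohort(p, seed = 11)
  b <- simulate_cohort(p, seed = 11)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  expect_false(identical(simulate_cohort(p, seed = 12)$samples, a$samples))
})

test_that("blinks are ocular: both eyes lose gaze and pupil together", {
  p <- noiseless_params(blink_rate_hz = 0.5)
  co <- simulate_cohort(p, seed = 5)
  na_lp <- is.na(co$samples$lp)
  expect_gt(sum(na_lp), 0)
  expect_identical(na_lp, is.na(co$samples$rp))
  expect_identical(na_lp, is.na(co$samples$lx))
  expect_identical(na_lp, is.na(co$samples$ry))
})

test_that("silent noise-free trials have a flat pupil trace and zero dilation", {
  p <- noiseless_params()
  sched <- generate_schedule(4, p$design)
  silent <- sched$trials[sched$trials$content == "silent", ][1, ]
  r <- simulate_trial(silent, params = p, seed = 2)
  expect_equal(diff(range(r$series$lp)), 0)
  expect_equal(r$truth$true_dilation_mm, 0)
  # non-silent trial has a positive event-locked response
  loud <- sched$trials[sched$trials$volume == "high", ][1, ]
  r2 <- simulate_trial(loud, params = p, seed = 2)
  expect_gt(r2$truth$true_dilation_mm, 0.05)
  expect_gt(diff(range(r2$series$lp)), 0.1)
})

test_that("noise-free dilation equals the kernel window mean times the gain", {
  p <- noiseless_params(measure_smooth_ms = 0, fs = 300)
  co <- simulate_cohort(p, seed = 6)
  ft <- preprocess_trials(co$samples, co$events,
                          pipeline_config(smooth_window_ms = 0, fs = 300))
  m <- merge(ft, co$events[, c("id", "trial_index", "isi_s", "volume")],
             by.x = c("id", "trial"), by.y = c("id", "trial_index"))
  m <- merge(m, co$truth, by = c("id", "trial"))
  # independent kernel formula, evaluated on the same grid as the recording
  grid_mean <- function(isi, from, to) {
    so <- p$sound_onset_s
    tt <- seq(0, so + isi + 3.5, by = 1 / p$fs)
    tk <- tt - so
    k <- ifelse(tk > 0, (tk / (12 * 0.08))^12 * exp(12 - tk / 0.08), 0)
    mean(k[tt >= from & tt < to])
  }
  ns <- m[m$volume != "none", ]
  for (i in seq_len(nrow(ns))) {
    gain <- p$dilation_gain_mm[[ns$volume[i]]]
    vo <- p$sound_onset_s + ns$isi_s[i]
    expected <- gain / p$kernel_wm_ref *
      (grid_mean(ns$isi_s[i], vo, vo + 2) -
         grid_mean(ns$isi_s[i], p$sound_onset_s - 0.2, p$sound_onset_s))
    expect_equal(ns$dilation_mm[i], expected, tolerance = 1e-9)
  }
  # and the analytic (incomplete-gamma) window mean agrees closely
  wm_grid <- sapply(ns$isi_s, function(isi)
    grid_mean(isi, p$sound_onset_s + isi, p$sound_onset_s + isi + 2))
  wm_analytic <- kernel_window_mean(ns$isi_s, ns$isi_s + 2)
  expect_equal(wm_grid, wm_analytic, tolerance = 1e-3)
})

test_that("volume-ordered dilation gains are visible in simulated cohorts", {
  p <- sim_params(n_per_age = c("5mo" = 6L, "10mo" = 6L), fs = 300)
  co <- simulate_cohort(p, seed = 8)   # 672 trials
  tr <- merge(co$truth, co$events[, c("id", "trial_index", "volume")],
              by.x = c("id", "trial"), by.y = c("id", "trial_index"))
  mh <- mean(tr$true_dilation_mm[tr$volume == "high"])
  ml <- mean(tr$true_dilation_mm[tr$volume == "low"])
  ms <- mean(tr$true_dilation_mm[tr$volume == "none"])
  expect_gt(mh, ml)
  expect_gt(ml, ms)
  expect_lt(abs((mh - ml) - 0.02), 0.012)  # ~4 x MC SE
})

test_that("the injected age effect on latency appears in cohort means", {
  # sample-mean oracle at > 500 valid trials per age group
  p <- sim_params(n_per_age = c("5mo" = 10L, "10mo" = 10L), fs = 300,
                  latency_infant_sdlog = 0, p_latency_low = 0,
                  p_latency_high = 0)
  co <- simulate_cohort(p, seed = 9)
  tr <- merge(co$truth, co$participants, by = "id")
  m5 <- mean(tr$true_latency_s[tr$age == "5mo"])
  m10 <- mean(tr$true_latency_s[tr$age == "10mo"])
  # lognormal sd ~ 0.12 s, n = 560/age -> MC SE of the difference ~ 0.007
  expect_lt(abs((m10 - m5) - (-0.09)), 0.021)
  expect_true(all(tr$true_latency_s >= 0.2 & tr$true_latency_s <= 1.0))
})

test_that("between-infant variance collapses when the intercept SD is zero", {
  p <- noiseless_params(n_per_age = c("5mo" = 3L, "10mo" = 3L), fs = 300)
  co <- simulate_cohort(p, seed = 10)
  ft <- preprocess_trials(co$samples, co$events, pipeline_config(fs = 300))
  bl <- merge(ft, co$participants, by = "id")
  per_infant <- tapply(bl$baseline_mm, bl$id, mean)
  ages <- tapply(as.character(bl$age), bl$id, `[`, 1)
  for (a in unique(ages)) {
    expect_lt(stats::sd(per_infant[ages == a]), 1e-9)
  }
})

test_that("simulation parameters are validated", {
  expect_error(sim_params(blink_rate_hz = -1), ">= 0")
  expect_error(sim_params(baseline_pupil_mm = c("5mo" = 1.0, "10mo" = 4.4)),
               "1.5-9 mm")
  expect_error(sim_params(dilation_gain_mm = c(high = 0.05, low = 0.07,
                                               none = 0)), "ordered")
})
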