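# Synthetic binocular eye-tracking sessions (gaze + pupil at 600 Hz) with
# known injected effects, so every downstream stage is testable without real
# recordings. One session = one infant running one 56-trial schedule.
#
# Trial timeline (seconds from trial start): centre fixation from 0;
# sound onset at `sound_onset_s`; visual array at sound onset + ISI, shown
# for 3 s; white screen for 0.5 s to trial end. The pupil signal is
# baseline + infant intercept + trial tonic jitter + slow drift +
# amplitude x Erlang kernel locked to the sound onset, plus sample noise;
# the two eyes differ by a constant offset plus independent noise. Gaze
# dwells at the centre, then saccades to the chosen AOI at the drawn
# latency. Blinks are binocular missing runs; off-screen episodes move gaze
# outside the screen bounds.

#' Event-locked pupil response kernel
#'
#' Erlang-shaped impulse response `(t / (shape*tau))^shape * exp(shape - t/tau)`,
#' peak-normalised to 1 at `t = shape * tau` (0.96 s after sound onset with
#' the defaults), essentially returned to baseline by ~2.5 s.
#'
#' @param t time since sound onset, seconds (values <= 0 give 0).
#' @param shape,tau_s kernel shape and time constant.
#' @return Kernel values.
#' @export
pupil_kernel <- function(t, shape = 12, tau_s = 0.08) {
  out <- numeric(length(t))
  pos <- !is.na(t) & t > 0
  out[pos] <- exp(shape * log(t[pos] / (shape * tau_s)) + shape - t[pos] / tau_s)
  out[is.na(t)] <- NA_real_
  out
}

#' Closed-form window mean of the pupil kernel
#'
#' Mean of the peak-normalised kernel over `[from, to)`, computed from the
#' regularised incomplete gamma function.
#'
#' @param from,to window bounds, seconds after sound onset.
#' @param shape,tau_s kernel parameters.
#' @return The analytic window mean.
#' @export
kernel_window_mean <- function(from, to, shape = 12, tau_s = 0.08) {
  # integral of (t/(s*tau))^s exp(s - t/tau) dt over [from, to]
  const <- exp(shape - shape * log(shape * tau_s)) *
    exp(lgamma(shape + 1) + (shape + 1) * log(tau_s))
  mass <- const * (stats::pgamma(to, shape + 1, rate = 1 / tau_s) -
                   stats::pgamma(pmax(from, 0), shape + 1, rate = 1 / tau_s))
  mass / (to - from)
}

# mean truncated-lognormal of X | a <= X <= b
trunc_lnorm_mean_ <- function(mu, sig, a, b) {
  num <- exp(mu + sig^2 / 2) *
    (stats::pnorm((log(b) - mu - sig^2) / sig) -
     stats::pnorm((log(a) - mu - sig^2) / sig))
  den <- stats::pnorm((log(b) - mu) / sig) - stats::pnorm((log(a) - mu) / sig)
  num / den
}

#' Simulation parameters
#'
#' Defaults encode the study conditions the analysis assumes: 25 + 21
#' infants (5- and 10-month groups) x 56 trials at 600 Hz; volume-ordered
#' dilation gains (high 0.09, low 0.07, silent 0 mm); an age effect of
#' -0.09 s on first-look latency; an age effect of 0.94 log-odds (and a
#' high-volume first-presentation effect of 0.44, and a 0.09 slope on
#' standardised dilation) on face selection. Dilation gains are calibrated
#' so the expected measured dilation (response-window mean minus baseline)
#' equals the nominal gain; latency lognormal locations are calibrated so
#' the truncated means equal the configured age-group means.
#'
#' @param n_per_age named infant counts per age group.
#' @param fs sampling rate, Hz.
#' @param sound_onset_s sound onset relative to trial start, seconds.
#' @param visual_dur_s,post_white_s visual array and trailing white-screen
#'   durations, seconds.
#' @param baseline_pupil_mm mean baseline pupil per age group, mm.
#' @param random_intercept_sd_mm between-infant SD of baseline pupil, mm.
#' @param tonic_jitter_sd_mm per-trial SD of slow baseline fluctuation, mm.
#' @param drift_slope_sd_mm_s SD of a within-trial linear drift slope, mm/s.
#' @param dilation_gain_mm named expected dilation per volume condition, mm;
#'   must be ordered high >= low >= none.
#' @param gain_jitter_sd_mm per-trial SD of the dilation amplitude, mm
#'   (sound trials only).
#' @param dilation_intercept_sd_mm between-infant SD of dilation amplitude, mm.
#' @param kernel_shape,kernel_tau_s response kernel parameters.
#' @param measure_smooth_ms smoothing window of the measurement definition
#'   under which ground-truth dilation is recorded (the protocol's 100 ms
#'   moving average; set to 0 together with the pipeline's
#'   `smooth_window_ms = 0` for raw-kernel window means).
#' @param latency_mean_s mean first-look latency per age group, seconds
#'   (valid-range trials).
#' @param latency_sdlog lognormal scale of latency.
#' @param latency_infant_sdlog between-infant SD on the lognormal location.
#' @param latency_isi_slope slope of the lognormal location on (ISI - 0.24) s.
#' @param latency_valid_range_s analysis validity range for latency, seconds.
#' @param p_latency_low,p_latency_high fraction of trials drawn below /
#'   above the valid latency range (exercises rejection criterion 5).
#' @param face_pref logistic coefficients for first-look-to-face:
#'   intercept, age (10 mo = 1), high-volume x first-presentation indicator,
#'   and slope on standardised dilation amplitude.
#' @param face_intercept_sd between-infant SD on the face-model intercept.
#' @param blink_rate_hz blink events per second (binocular).
#' @param blink_dur_mean_s,blink_dur_sd_s blink duration distribution, seconds.
#' @param offscreen_rate probability per trial of one off-screen episode.
#' @param offscreen_dur_s duration range of off-screen episodes, seconds.
#' @param attrition_sdlog between-infant lognormal SD multiplying blink and
#'   off-screen rates (some infants are fussier than others).
#' @param eye_offset_mm constant left-minus-right pupil size offset, mm.
#' @param pupil_noise_sd_mm per-sample pupil measurement noise, mm.
#' @param gaze_noise_sd_deg per-sample, per-eye gaze noise, degrees.
#' @param prop_male probability an infant is male.
#' @param design experiment design from [design_config()].
#' @return A `sim_params` list (with derived calibration constants).
#' @export
sim_params <- function(n_per_age = c("5mo" = 25L, "10mo" = 21L),
                       fs = 600,
                       sound_onset_s = 0.6,
                       visual_dur_s = 3.0,
                       post_white_s = 0.5,
                       baseline_pupil_mm = c("5mo" = 4.6, "10mo" = 4.4),
                       random_intercept_sd_mm = 0.3,
                       tonic_jitter_sd_mm = 0.10,
                       drift_slope_sd_mm_s = 0.02,
                       dilation_gain_mm = c(high = 0.09, low = 0.07, none = 0),
                       gain_jitter_sd_mm = 0.05,
                       dilation_intercept_sd_mm = 0.02,
                       kernel_shape = 12,
                       kernel_tau_s = 0.08,
                       measure_smooth_ms = 100,
                       latency_mean_s = c("5mo" = 0.445, "10mo" = 0.355),
                       latency_sdlog = 0.25,
                       latency_infant_sdlog = 0.08,
                       latency_isi_slope = 0,
                       latency_valid_range_s = c(0.2, 1.0),
                       p_latency_low = 0.012,
                       p_latency_high = 0.005,
                       face_pref = c(intercept = -0.62, age = 0.94,
                                     high_first = 0.44, dilation_z = 0.09),
                       face_intercept_sd = 0.4,
                       blink_rate_hz = 0.10,
                       blink_dur_mean_s = 0.25,
                       blink_dur_sd_s = 0.08,
                       offscreen_rate = 0.05,
                       offscreen_dur_s = c(0.3, 1.0),
                       attrition_sdlog = 0.5,
                       eye_offset_mm = 0.2,
                       pupil_noise_sd_mm = 0.05,
                       gaze_noise_sd_deg = 0.5,
                       prop_male = 0.5,
                       design = design_config()) {
  p <- as.list(environment())
  rates <- c(p$blink_rate_hz, p$offscreen_rate, p$gain_jitter_sd_mm,
             p$pupil_noise_sd_mm, p$gaze_noise_sd_deg, p$tonic_jitter_sd_mm,
             p$random_intercept_sd_mm, p$p_latency_low, p$p_latency_high)
  if (any(rates < 0)) stop("sim_params: rates and noise SDs must be >= 0")
  if (any(p$baseline_pupil_mm < 1.5 | p$baseline_pupil_mm > 9)) {
    stop("sim_params: baseline pupil must lie in the 1.5-9 mm validity range")
  }
  g <- p$dilation_gain_mm
  if (!(g[["high"]] >= g[["low"]] && g[["low"]] >= g[["none"]])) {
    stop("sim_params: dilation gains must be ordered high >= low >= none")
  }
  if (!identical(sort(names(p$n_per_age)), sort(names(p$baseline_pupil_mm)))) {
    stop("sim_params: age-group names must match across parameters")
  }
  # amplitude calibration: average kernel response-window mean over the ISI
  # distribution, so that E[measured dilation] = nominal gain
  isis <- seq(design$isi_range_s[1], design$isi_range_s[2], length.out = 33)
  p$kernel_wm_ref <- mean(kernel_window_mean(isis, isis + 2,
                                             p$kernel_shape, p$kernel_tau_s))
  # latency location calibration: truncated mean hits the configured mean
  a <- p$latency_valid_range_s[1]; b <- p$latency_valid_range_s[2]
  p$latency_mu <- vapply(p$latency_mean_s, function(m) {
    stats::uniroot(function(mu) trunc_lnorm_mean_(mu, p$latency_sdlog, a, b) - m,
                   interval = log(m) + c(-1, 1), tol = 1e-10)$root
  }, numeric(1))
  class(p) <- "sim_params"
  p
}

# Core generator: given an event table (one row per trial, schedule columns +
# infant id) and an infant table, draw everything and emit sample arrays.
# Assumes an active RNG stream.
sim_core_ <- function(ev, infants, params) {
  ds <- params$design
  fs <- params$fs
  nt <- nrow(ev)
  inf <- match(ev$id, infants$id)
  age10 <- infants$age[inf] == names(params$n_per_age)[2]

  ev$sound_onset_s <- params$sound_onset_s
  ev$visual_onset_s <- ev$sound_onset_s + ev$isi_s
  ev$visual_offset_s <- ev$visual_onset_s + params$visual_dur_s
  ev$trial_end_s <- ev$visual_offset_s + params$post_white_s

  nsamp <- as.integer(floor(ev$trial_end_s * fs + 1e-9)) + 1L
  N <- sum(nsamp)
  row <- rep.int(seq_len(nt), nsamp)
  t <- (sequence(nsamp) - 1L) / fs

  # --- pupil signal -------------------------------------------------------
  nonsil <- ev$volume != "none"
  # additive amplitude variability (not truncated, so condition means equal
  # the nominal gains exactly; a mildly negative single-trial amplitude is
  # trial-level constriction)
  amp_mm <- unname(params$dilation_gain_mm[ev$volume]) +
    (stats::rnorm(nt, 0, params$gain_jitter_sd_mm) +
       infants$u_dil[inf]) * nonsil
  amp <- amp_mm / params$kernel_wm_ref
  base_trial <- unname(params$baseline_pupil_mm[infants$age[inf]]) +
    infants$u_base[inf] + stats::rnorm(nt, 0, params$tonic_jitter_sd_mm)
  slope_trial <- stats::rnorm(nt, 0, params$drift_slope_sd_mm_s)

  k <- pupil_kernel(t - ev$sound_onset_s[row], params$kernel_shape,
                    params$kernel_tau_s)
  sig <- base_trial[row] + amp[row] * k + slope_trial[row] * t
  lp <- sig + params$eye_offset_mm / 2 +
    stats::rnorm(N, 0, params$pupil_noise_sd_mm)
  rp <- sig - params$eye_offset_mm / 2 +
    stats::rnorm(N, 0, params$pupil_noise_sd_mm)

  # injected (true) dilation: amplitude x kernel window means (response
  # minus baseline window) on the trial's own sample grid, under the
  # protocol's measurement definition (100 ms moving-average filter)
  vo <- ev$visual_onset_s[row]; so <- ev$sound_onset_s[row]
  hw <- ma_halfwidth_(params$measure_smooth_ms, fs)
  km <- if (hw > 0L) moving_avg_(k, row, hw) else k
  kdt <- data.table::data.table(g = row, k = km)
  rm_ <- kdt[t >= vo & t < vo + 2, list(resp = mean(k)), by = "g"]
  bm_ <- kdt[t >= so - 0.2 & t < so, list(base = mean(k)), by = "g"]
  kresp <- numeric(nt); kresp[rm_$g] <- rm_$resp
  kbase <- numeric(nt); kbase[bm_$g] <- bm_$base
  true_dil <- amp * (kresp - kbase)

  # --- latency and first-look target --------------------------------------
  a <- params$latency_valid_range_s[1]; b <- params$latency_valid_range_s[2]
  mu_i <- unname(params$latency_mu[infants$age[inf]]) + infants$u_lat[inf] +
    params$latency_isi_slope * (ev$isi_s - 0.24)
  u01 <- stats::runif(nt)
  cls <- ifelse(u01 < params$p_latency_low, "low",
         ifelse(u01 < params$p_latency_low + params$p_latency_high, "high",
                "valid"))
  lat <- numeric(nt)
  iv <- cls == "valid"
  uu <- stats::runif(sum(iv), stats::plnorm(a, mu_i[iv], params$latency_sdlog),
                     stats::plnorm(b, mu_i[iv], params$latency_sdlog))
  lat[iv] <- stats::qlnorm(uu, mu_i[iv], params$latency_sdlog)
  lat[cls == "low"] <- stats::runif(sum(cls == "low"), 0.08, a - 2 / fs)
  lat[cls == "high"] <- stats::runif(sum(cls == "high"), b + 2 / fs,
                                     params$visual_dur_s - 0.3)

  sd_dil <- stats::sd(true_dil)
  dil_z <- if (is.na(sd_dil) || sd_dil == 0) {
    rep(0, nt)
  } else {
    (true_dil - mean(true_dil)) / sd_dil
  }
  fp <- params$face_pref
  eta <- fp[["intercept"]] + fp[["age"]] * age10 +
    fp[["high_first"]] * (ev$volume == "high" & ev$order_in_pair == "first") +
    fp[["dilation_z"]] * dil_z + infants$u_face[inf]
  isface <- stats::runif(nt) < stats::plogis(eta)
  others <- matrix(rep(setdiff(ds$categories, "face"), each = nt), nrow = nt)
  target <- ifelse(isface, "face",
                   others[cbind(seq_len(nt), sample.int(3L, nt, replace = TRUE))])
  posmat <- as.matrix(ev[, paste0("pos_", ds$categories), with = FALSE])
  target_pos <- posmat[cbind(seq_len(nt), match(target, ds$categories))]

  # --- gaze ---------------------------------------------------------------
  gx <- ds$positions$x[target_pos]
  gy <- ds$positions$y[target_pos]
  shifted <- t >= (ev$visual_onset_s + lat)[row]
  x0 <- gx[row] * shifted
  y0 <- gy[row] * shifted

  # off-screen episodes (gaze tracked but outside the screen)
  attr_m <- infants$attrition[inf]
  has_off <- stats::runif(nt) < params$offscreen_rate * attr_m
  off_dur <- stats::runif(nt, params$offscreen_dur_s[1], params$offscreen_dur_s[2])
  off_t0 <- stats::runif(nt) * pmax(ev$trial_end_s - off_dur, 0)
  offmask <- has_off[row] & t >= off_t0[row] & t < (off_t0 + off_dur)[row]
  x0[offmask] <- 24
  y0[offmask] <- 14

  gn <- params$gaze_noise_sd_deg
  lx <- x0 + stats::rnorm(N, 0, gn); ly <- y0 + stats::rnorm(N, 0, gn)
  rx <- x0 + stats::rnorm(N, 0, gn); ry <- y0 + stats::rnorm(N, 0, gn)

  # --- blinks: binocular missing runs -------------------------------------
  nb <- stats::rpois(nt, params$blink_rate_hz * attr_m * ev$trial_end_s)
  if (sum(nb) > 0) {
    btrial <- rep.int(seq_len(nt), nb)
    bt0 <- stats::runif(sum(nb), 0, ev$trial_end_s[btrial])
    bdur <- pmax(stats::rnorm(sum(nb), params$blink_dur_mean_s,
                              params$blink_dur_sd_s), 0.05)
    offs <- cumsum(nsamp) - nsamp
    i0 <- offs[btrial] + pmax(as.integer(ceiling(bt0 * fs)), 0L) + 1L
    i1 <- offs[btrial] + pmin(as.integer(floor((bt0 + bdur) * fs)) + 1L,
                              nsamp[btrial])
    len <- i1 - i0 + 1L
    keep <- len > 0L
    if (any(keep)) {
      idx <- sequence(len[keep], from = i0[keep])
      lx[idx] <- NA_real_; ly[idx] <- NA_real_
      rx[idx] <- NA_real_; ry[idx] <- NA_real_
      lp[idx] <- NA_real_; rp[idx] <- NA_real_
    }
  }

  samples <- data.table::data.table(
    id = ev$id[row], trial = ev$trial_index[row], t = t,
    lx = lx, ly = ly, rx = rx, ry = ry, lp = lp, rp = rp)
  truth <- data.table::data.table(
    id = ev$id, trial = ev$trial_index,
    true_latency_s = lat, latency_class = cls,
    true_target = target, true_target_pos = target_pos,
    true_dilation_mm = true_dil, true_face = isface)
  list(samples = samples, events = ev, truth = truth)
}

#' Simulate a full cohort of sessions
#'
#' Generates one counterbalanced schedule per infant (each with its own
#' derived seed), draws per-infant random intercepts once, and simulates
#' every trial. Ground truth (drawn latencies, chosen targets, injected
#' dilation amplitudes) is returned separately and is never read by the
#' analysis pipeline.
#'
#' @param params simulation parameters from [sim_params()].
#' @param seed integer seed; the cohort is deterministic given the seed.
#' @return List with `samples` (long sample table), `events` (one row per
#'   trial), `truth`, `participants`, and `params`.
#' @export
simulate_cohort <- function(params = sim_params(), seed = 1) {
  with_seed_(seed, {
    ages <- rep(names(params$n_per_age), params$n_per_age)
    n_inf <- length(ages)
    infants <- data.table::data.table(
      id = sprintf("p%03d", seq_len(n_inf)),
      age = ages,
      sex = ifelse(stats::runif(n_inf) < params$prop_male, "male", "female"),
      u_base = stats::rnorm(n_inf, 0, params$random_intercept_sd_mm),
      u_dil = stats::rnorm(n_inf, 0, params$dilation_intercept_sd_mm),
      u_lat = stats::rnorm(n_inf, 0, params$latency_infant_sdlog),
      u_face = stats::rnorm(n_inf, 0, params$face_intercept_sd),
      attrition = stats::rlnorm(n_inf, 0, params$attrition_sdlog))
    sched_seeds <- sample.int(.Machine$integer.max - 1L, n_inf)
    ev <- data.table::rbindlist(lapply(seq_len(n_inf), function(i) {
      s <- generate_schedule(sched_seeds[i], params$design)
      tr <- data.table::as.data.table(s$trials)
      tr[, id := infants$id[i]]
      tr
    }))
    res <- sim_core_(ev, infants, params)
    res$participants <- infants[, c("id", "age", "sex")]
    res$params <- params
    res
  })
}

#' Simulate a single trial
#'
#' Convenience wrapper around the cohort generator for one trial of one
#' infant; returns the sample series plus the ground-truth record.
#'
#' @param trial one row of a schedule's `trials` table.
#' @param infant_state optional list with `age`, `u_base`, `u_dil`, `u_lat`,
#'   `u_face`, `attrition` (defaults: first age group, all zero, 1).
#' @param params simulation parameters.
#' @param seed integer seed.
#' @return List with `series` (data frame), `events` (one row) and `truth`.
#' @export
simulate_trial <- function(trial, infant_state = NULL, params = sim_params(),
                           seed = 1) {
  st <- utils::modifyList(
    list(age = names(params$n_per_age)[1], sex = "female",
         u_base = 0, u_dil = 0, u_lat = 0, u_face = 0, attrition = 1),
    if (is.null(infant_state)) list() else infant_state)
  infants <- data.table::data.table(
    id = "p001", age = st$age, sex = st$sex, u_base = st$u_base,
    u_dil = st$u_dil, u_lat = st$u_lat, u_face = st$u_face,
    attrition = st$attrition)
  ev <- data.table::as.data.table(trial)
  ev[, id := "p001"]
  res <- with_seed_(seed, sim_core_(ev, infants, params))
  list(series = as.data.frame(res$samples[, -c("id", "trial")]),
       events = res$events, truth = res$truth)
}
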