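# Pupil preprocessing chain and derived measures. The pipeline order follows
# the measurement definition: smooth (per eye) -> dynamic-offset binocular
# mean -> validity recoding (absolute range, then +-k SD about the trial
# mean, then off-screen gaze) -> gap interpolation -> baseline / response
# window means -> dilation.

#' Moving-average smoothing of a pupil trace
#'
#' Centred moving average over valid samples within a `window_ms` window
#' (61 samples at 600 Hz for the default 100 ms, endpoints included).
#' Missing samples remain missing; edges use the truncated window.
#'
#' @param x pupil samples, mm (NA = missing).
#' @param t sample times, seconds.
#' @param window_ms smoothing window length, ms. `0` disables smoothing.
#' @param fs nominal sampling rate, Hz (inferred from `t` if `NULL`).
#' @return Smoothed numeric vector.
#' @export
smooth_pupil <- function(x, t, window_ms = 100, fs = NULL) {
  if (window_ms <= 0) return(x)
  if (is.null(fs)) fs <- 1 / sample_period_(t)
  moving_avg_(x, halfwidth = ma_halfwidth_(window_ms, fs))
}

#' Dynamic-offset binocular pupil mean
#'
#' Averages the two smoothed pupil traces taking into account the dynamic
#' offset between the two pupils in gaps where one eye is missing: the
#' left-right offset observed on both-valid samples is linearly interpolated
#' (nearest-edge extrapolated) across one-eye gaps, and the available eye is
#' shifted by half the reconstructed offset. If the trial has no both-valid
#' sample, falls back to the plain available-eye mean and flags the trial.
#'
#' @param left,right per-eye pupil traces, mm.
#' @param t sample times, seconds.
#' @return List with `pupil` (merged trace) and `fallback` (logical flag).
#' @export
dynamic_offset_mean <- function(left, right, t) {
  res <- offset_mean_(left, right, t)
  list(pupil = res$pupil, fallback = isTRUE(res$fallback))
}

#' Recode invalid pupil samples to missing
#'
#' Three recoding passes in order: (1) samples outside the absolute validity
#' range; (2) samples more than `sd_k` standard deviations from the trial
#' mean, with mean/SD computed once after the range pass; (3) samples where
#' gaze was detected outside the screen.
#'
#' @param x merged pupil trace, mm.
#' @param range_mm absolute validity range, mm.
#' @param sd_k standard-deviation cutoff.
#' @param offscreen_mask logical mask (same grid) of samples with gaze
#'   detected outside the screen; `NULL` skips the pass.
#' @return Recoded numeric vector.
#' @export
recode_invalid <- function(x, range_mm = c(1.5, 9), sd_k = 3,
                           offscreen_mask = NULL) {
  x <- recode_range_(x, range_mm)
  x <- recode_sd_(x, k = sd_k)
  if (!is.null(offscreen_mask)) x[offscreen_mask] <- NA_real_
  x
}

#' Interpolate pupil over short gaps
#'
#' Same contract as [interpolate_gaze()] applied to the scalar pupil channel:
#' linear interpolation over gaps strictly shorter than `max_gap_ms`.
#'
#' @param x pupil trace, mm.
#' @param t sample times, seconds (strictly increasing).
#' @param max_gap_ms maximum gap duration to fill, ms (exclusive bound).
#' @return Interpolated numeric vector.
#' @export
interpolate_pupil <- function(x, t, max_gap_ms = 150) {
  stop_if_nonmonotone_(t)
  gap_fill_(x, t, max_gap_s = max_gap_ms / 1000)
}

# mean + missing fraction over a half-open time window [from, to)
window_mean_ <- function(x, t, from, to) {
  w <- t >= from & t < to
  if (!any(w)) return(list(mean = NA_real_, prop_missing = 1))
  xs <- x[w]
  m <- mean(xs, na.rm = TRUE)
  list(mean = if (is.nan(m)) NA_real_ else m,
       prop_missing = mean(is.na(xs)))
}

#' Baseline pupil size
#'
#' Mean interpolated pupil size over the `window_ms` preceding the sound
#' onset (half-open window, valid samples only). Silent trials carry the
#' corresponding marker.
#'
#' @param x interpolated pupil trace, mm.
#' @param t sample times, seconds.
#' @param sound_onset_s sound onset (or equivalent marker), seconds.
#' @param window_ms baseline window length, ms.
#' @return List with `baseline_mm` and `prop_missing`.
#' @export
baseline_pupil <- function(x, t, sound_onset_s, window_ms = 200) {
  r <- window_mean_(x, t, sound_onset_s - window_ms / 1000, sound_onset_s)
  list(baseline_mm = r$mean, prop_missing = r$prop_missing)
}

#' Response pupil size
#'
#' Mean interpolated pupil size over the first `window_s` seconds after the
#' visual array onset (half-open window, valid samples only).
#'
#' @param x interpolated pupil trace, mm.
#' @param t sample times, seconds.
#' @param visual_onset_s visual array onset, seconds.
#' @param window_s response window length, seconds.
#' @return List with `response_mm` and `prop_missing`.
#' @export
response_pupil <- function(x, t, visual_onset_s, window_s = 2.0) {
  r <- window_mean_(x, t, visual_onset_s, visual_onset_s + window_s)
  list(response_mm = r$mean, prop_missing = r$prop_missing)
}

#' Task-evoked pupil dilation
#'
#' Response minus baseline; `NA` when either input is missing.
#'
#' @param baseline_mm,response_mm window means from [baseline_pupil()] and
#'   [response_pupil()].
#' @return Dilation in mm.
#' @export
pupil_dilation <- function(baseline_mm, response_mm) {
  ifelse(is.na(baseline_mm) | is.na(response_mm), NA_real_,
         response_mm - baseline_mm)
}
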