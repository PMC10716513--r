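# Gaze preprocessing: gap interpolation, binocular averaging, AOI coding,
# first-entry latency, missingness statistics. A single-trial sample series
# is a data frame with columns t, lx, ly, rx, ry (gaze, visual degrees,
# screen-centred, rightward/upward positive) and optionally lp, rp (pupil,
# mm); missing samples are NA.

#' AOI geometry for the four-image array
#'
#' Four square areas of interest centred on the image positions, plus the
#' central attention-grabber area. With the default geometry (centres at
#' +-12 degrees horizontally, +-6 vertically; 11-degree sides) the image AOIs
#' are pairwise disjoint.
#'
#' @param positions data frame with columns `pos`, `x`, `y` (degrees).
#' @param side_deg side length of the square image AOIs, degrees.
#' @param central_side_deg side length of the central attention-grabber
#'   area, degrees.
#' @return A list with the AOI centres and half-sides.
#' @export
aoi_set <- function(positions = design_config()$positions,
                    side_deg = 11, central_side_deg = 6) {
  list(centers = positions, half = side_deg / 2,
       central_half = central_side_deg / 2)
}

#' Interpolate gaze over short gaps
#'
#' Linearly interpolates each gaze channel (per eye, per coordinate) over
#' gaps strictly shorter than `max_gap_ms`, measured from the last valid
#' sample to the next valid sample. Longer gaps and leading/trailing gaps
#' are left untouched.
#'
#' @param series single-trial sample data frame (strictly increasing `t`).
#' @param max_gap_ms maximum gap duration to fill, ms (exclusive bound).
#' @return The series with gaze channels interpolated.
#' @export
interpolate_gaze <- function(series, max_gap_ms = 150) {
  stop_if_nonmonotone_(series$t)
  for (ch in intersect(c("lx", "ly", "rx", "ry"), names(series))) {
    series[[ch]] <- gap_fill_(series[[ch]], series$t,
                              max_gap_s = max_gap_ms / 1000)
  }
  series
}

#' Average the two eyes into a cyclopean gaze series
#'
#' Per sample and per coordinate, the mean of the available eyes; a sample is
#' missing only when both eyes are missing.
#'
#' @param series single-trial sample data frame.
#' @return Data frame with columns `t`, `x`, `y`.
#' @export
average_eyes <- function(series) {
  nanmean2 <- function(a, b) {
    out <- (a + b) / 2
    out[is.na(a)] <- b[is.na(a)]
    out[is.na(b)] <- a[is.na(b)]
    out
  }
  data.frame(t = series$t,
             x = nanmean2(series$lx, series$rx),
             y = nanmean2(series$ly, series$ry))
}

# Integer AOI code per sample: 1..4 for the image AOIs (position codes), 0
# when gaze is missing or in no AOI. Membership uses closed intervals.
aoi_code_ <- function(x, y, aois) {
  code <- integer(length(x))
  ok <- !is.na(x) & !is.na(y)
  for (j in seq_len(nrow(aois$centers))) {
    ins <- ok & abs(x - aois$centers$x[j]) <= aois$half &
      abs(y - aois$centers$y[j]) <= aois$half
    code[ins & code == 0L] <- aois$centers$pos[j]
  }
  code
}

#' Per-sample AOI indicator vectors
#'
#' Binary indicator per image AOI; missing gaze codes as 0 everywhere. The
#' AOIs are disjoint, so at most one indicator is active per sample.
#'
#' @param gaze cyclopean gaze data frame (`t`, `x`, `y`).
#' @param aois AOI geometry from [aoi_set()].
#' @return Integer matrix `n x 4`, columns named by position code.
#' @export
aoi_vectors <- function(gaze, aois = aoi_set()) {
  code <- aoi_code_(gaze$x, gaze$y, aois)
  out <- vapply(aois$centers$pos, function(p) as.integer(code == p),
                integer(nrow(gaze)))
  colnames(out) <- aois$centers$pos
  out
}

#' First AOI entry latency
#'
#' Scans AOI entries (maximal runs of consecutive samples inside one AOI) in
#' temporal order across all AOIs during the visual presentation and returns
#' the onset of the first entry lasting at least `min_dwell_ms` (run duration
#' = sample count x nominal period). Latency is measured from the visual
#' onset to the first accepted sample. A run broken by a single missing
#' sample is broken.
#'
#' @param indicators AOI indicator matrix from [aoi_vectors()] (or an
#'   integer AOI code vector).
#' @param t sample times, seconds.
#' @param visual_onset_s visual array onset, seconds.
#' @param visual_offset_s end of the visual presentation, seconds.
#' @param min_dwell_ms minimum entry duration, ms.
#' @param fs nominal sampling rate, Hz (inferred from `t` if `NULL`).
#' @return List with `latency_s` and `aoi` (position code), both `NA` when no
#'   qualifying entry exists.
#' @export
first_entry_latency <- function(indicators, t, visual_onset_s,
                                visual_offset_s = Inf, min_dwell_ms = 100,
                                fs = NULL) {
  code <- if (is.matrix(indicators)) {
    cols <- as.integer(colnames(indicators))
    as.integer(indicators %*% cols)
  } else {
    as.integer(indicators)
  }
  if (is.null(fs)) fs <- 1 / sample_period_(t)
  vis <- t >= visual_onset_s & t < visual_offset_s
  cv <- ifelse(vis, code, -1L)
  r <- rle(cv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  need <- dwell_samples_(min_dwell_ms, fs)
  acc <- which(r$values > 0L & r$lengths >= need)
  if (!length(acc)) return(list(latency_s = NA_real_, aoi = NA_integer_))
  k <- acc[1L]
  list(latency_s = t[starts[k]] - visual_onset_s, aoi = r$values[k])
}

#' Gaze missingness statistics
#'
#' Proportion of raw missing data (both eyes absent, before interpolation)
#' over the whole trial, and proportion of on-screen data during the visual
#' presentation (after interpolation). On-screen means gaze present and
#' inside the screen bounds.
#'
#' @param raw_series raw single-trial series (before interpolation).
#' @param interp_series the same series after [interpolate_gaze()].
#' @param visual_onset_s,visual_offset_s visual presentation window, seconds.
#' @param screen_half_deg half-extent of the screen, degrees `c(x, y)`.
#' @return List with `prop_raw_missing` and `prop_onscreen_visual`.
#' @export
missingness_stats <- function(raw_series, interp_series, visual_onset_s,
                              visual_offset_s,
                              screen_half_deg = c(21.5, 12.5)) {
  miss_raw <- (is.na(raw_series$lx) | is.na(raw_series$ly)) &
    (is.na(raw_series$rx) | is.na(raw_series$ry))
  cyc <- average_eyes(interp_series)
  vis <- cyc$t >= visual_onset_s & cyc$t < visual_offset_s
  onscreen <- !is.na(cyc$x) & !is.na(cyc$y) &
    abs(cyc$x) <= screen_half_deg[1] & abs(cyc$y) <= screen_half_deg[2]
  list(prop_raw_missing = mean(miss_raw),
       prop_onscreen_visual = if (any(vis)) mean(onscreen[vis]) else NA_real_)
}
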