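# Whole-cohort preprocessing engine. Applies the gaze chain (interpolate per
# eye -> cyclopean average -> AOI coding -> first-entry latency ->
# missingness stats) and the pupil chain (smooth per eye -> dynamic-offset
# mean -> range / SD / off-screen recoding -> interpolate -> window means)
# to every trial at once, using the grouped vector primitives in signal.R.
# The per-operation functions in gaze.R / pupil.R share those primitives, so
# a single trial run through this engine matches the per-trial operations
# exactly.

#' Pipeline configuration
#'
#' All preprocessing and screening tunables, with the measurement protocol's
#' values as defaults: 150 ms interpolation gap bound, 100 ms smoothing
#' window, 11-degree AOIs, 1.5-9 mm pupil validity range, 3 SD trial cutoff,
#' 200 ms baseline and 2 s response windows, 40% / 25% criterion occupancy
#' bounds, 0.2-1.0 s latency validity, 70% participant inclusion, m = 100
#' imputations.
#'
#' @param ... named overrides of any default.
#' @return A configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fs = 600,
    gaze_max_gap_ms = 150,
    pupil_max_gap_ms = 150,
    smooth_window_ms = 100,
    pupil_range_mm = c(1.5, 9),
    pupil_sd_k = 3,
    aoi_side_deg = 11,
    central_side_deg = 6,
    screen_half_deg = c(21.5, 12.5),
    baseline_window_ms = 200,
    response_window_s = 2,
    min_dwell_ms = 100,
    c1_window_s = 0.5,
    c1_occupancy = 0.40,
    c2_window_s = 0.2,
    c3_mode = "any",          # one of "any", "all", "proportion"
    c3_prop = 0.25,
    latency_valid_s = c(0.2, 1.0),
    include_threshold = 0.70,
    dilation_standardize = "global",  # or "per_infant"
    m_imputations = 100
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

# scatter per-group values (indexed by group id 1..ng) into a full vector
gvec_ <- function(ng, idx, val, default = NA_real_) {
  out <- rep(default, ng)
  out[idx] <- val
  out
}

#' Preprocess all trials of a cohort
#'
#' Runs the full gaze and pupil preprocessing chains and returns one row of
#' derived measures and criterion-window statistics per trial.
#'
#' @param samples long sample table (`id`, `trial`, `t`, `lx`, `ly`, `rx`,
#'   `ry`, `lp`, `rp`), ordered by id, trial, t.
#' @param events trial event table (one row per `id` x `trial_index` with
#'   onset markers and image positions).
#' @param config pipeline configuration from [pipeline_config()].
#' @return `data.table` of per-trial features: missingness proportions,
#'   first-entry latency and AOI, time in each AOI, baseline / response /
#'   dilation pupil measures, and the window statistics consumed by
#'   [apply_trial_criteria()].
#' @export
preprocess_trials <- function(samples, events, config = pipeline_config()) {
  dt <- data.table::as.data.table(samples)
  ev <- data.table::copy(data.table::as.data.table(events))
  if (!"trial" %in% names(ev)) ev[, trial := trial_index]
  fs <- config$fs
  n <- nrow(dt)
  g <- data.table::rleid(dt$id, dt$trial)
  ng <- g[n]
  t <- dt$t
  stop_if_nonmonotone_(t, g)

  first <- !duplicated(g)
  gmap <- data.table::data.table(g = g[first], id = dt$id[first],
                                 trial = dt$trial[first])
  evj <- ev[gmap, on = c("id", "trial")]
  if (anyNA(evj$visual_onset_s)) {
    stop("events table is missing trials present in the samples")
  }
  so_g <- evj$sound_onset_s
  vo_g <- evj$visual_onset_s
  voff_g <- evj$visual_offset_s
  so <- so_g[g]; vo <- vo_g[g]; voff <- voff_g[g]

  gb <- group_bounds_(g, n)

  # ---- gaze chain --------------------------------------------------------
  miss_raw <- (is.na(dt$lx) | is.na(dt$ly)) & (is.na(dt$rx) | is.na(dt$ry))
  mg <- config$gaze_max_gap_ms / 1000
  ilx <- gap_fill_(dt$lx, t, g, mg, gb = gb)
  ily <- gap_fill_(dt$ly, t, g, mg, gb = gb)
  irx <- gap_fill_(dt$rx, t, g, mg, gb = gb)
  iry <- gap_fill_(dt$ry, t, g, mg, gb = gb)
  cx <- (ilx + irx) / 2; cx[is.na(ilx)] <- irx[is.na(ilx)]
  cx[is.na(irx)] <- ilx[is.na(irx)]
  cy <- (ily + iry) / 2; cy[is.na(ily)] <- iry[is.na(ily)]
  cy[is.na(iry)] <- ily[is.na(iry)]

  sh <- config$screen_half_deg
  present <- !is.na(cx) & !is.na(cy)
  inside <- present & abs(cx) <= sh[1] & abs(cy) <= sh[2]
  outside_detected <- present & !inside
  chalf <- config$central_side_deg / 2
  central <- inside & abs(cx) <= chalf & abs(cy) <= chalf
  bad <- !inside  # missing or outside the screen

  aois <- aoi_set(side_deg = config$aoi_side_deg,
                  central_side_deg = config$central_side_deg)
  code <- aoi_code_(cx, cy, aois)

  msk_vis <- t >= vo & t < voff
  msk_c1 <- t >= so - config$c1_window_s & t < so
  msk_c2 <- t >= vo - config$c2_window_s & t < vo
  msk_p1 <- t >= vo & t < vo + 0.5
  msk_p2 <- t >= vo + 0.5 & t < vo + 1.0
  # fraction of window samples where `val` holds, per trial (NA: empty window)
  grouped_frac <- function(mask, val) {
    idx <- g[mask]
    tot <- tabulate(idx, ng)
    hits <- tabulate(idx[val[mask]], ng)
    out <- hits / tot
    out[tot == 0L] <- NA_real_
    out
  }
  prop_onscreen_visual <- grouped_frac(msk_vis, inside)
  occ_central_presound <- grouped_frac(msk_c1, central)
  central_prop_previsual <- grouped_frac(msk_c2, central)
  bad_prop_post1 <- grouped_frac(msk_p1, bad)
  bad_prop_post2 <- grouped_frac(msk_p2, bad)
  prop_raw_missing <- tabulate(g[miss_raw], ng) / tabulate(g, ng)

  # ---- AOI entries: first accepted run and time in AOI -------------------
  cvis <- code
  cvis[!msk_vis] <- -1L
  change <- c(TRUE, cvis[-1L] != cvis[-n] | g[-1L] != g[-n])
  starts <- which(change)
  ends <- c(starts[-1L] - 1L, n)
  rg <- g[starts]; rcode <- cvis[starts]
  rn <- ends - starts + 1L; rt0 <- t[starts]
  need <- dwell_samples_(config$min_dwell_ms, fs)
  acc <- which(rcode > 0L & rn >= need)
  firstacc <- acc[!duplicated(rg[acc])]
  latency_s <- gvec_(ng, rg[firstacc], rt0[firstacc] - vo_g[rg[firstacc]])
  first_aoi <- gvec_(ng, rg[firstacc], rcode[firstacc], NA_integer_)

  aoi_time <- matrix(0, nrow = ng, ncol = 4,
                     dimnames = list(NULL, paste0("aoi_time_",
                                                  aois$centers$label)))
  inaoi <- cvis > 0L
  if (any(inaoi)) {
    comp <- (g[inaoi] - 1L) * 4L + cvis[inaoi]
    aoi_time[] <- t(matrix(tabulate(comp, ng * 4L), nrow = 4L)) / fs
  }

  # ---- pupil chain -------------------------------------------------------
  hw <- ma_halfwidth_(config$smooth_window_ms, fs)
  slp <- if (hw > 0L) moving_avg_(dt$lp, g, hw, gb = gb) else dt$lp
  srp <- if (hw > 0L) moving_avg_(dt$rp, g, hw, gb = gb) else dt$rp
  om <- offset_mean_(slp, srp, t, g, gb = gb)
  pp <- om$pupil
  pp <- recode_range_(pp, config$pupil_range_mm)
  pp <- recode_sd_(pp, g, config$pupil_sd_k)
  pp[outside_detected] <- NA_real_
  pp <- gap_fill_(pp, t, g, config$pupil_max_gap_ms / 1000, gb = gb)

  bw <- config$baseline_window_ms / 1000
  msk_b <- t >= so - bw & t < so
  msk_r <- t >= vo & t < vo + config$response_window_s
  pna <- is.na(pp)
  gw <- function(mask) {
    idx <- g[mask]
    tot <- tabulate(idx, ng)
    nmiss <- tabulate(idx[pna[mask]], ng)
    v0 <- pp[mask]
    v0[is.na(v0)] <- 0
    sums <- numeric(ng)
    rs <- rowsum(v0, idx)
    sums[as.integer(rownames(rs))] <- rs[, 1L]
    nvalid <- tot - nmiss
    m <- sums / nvalid
    m[nvalid == 0L] <- NA_real_
    miss <- nmiss / tot
    miss[tot == 0L] <- 1
    list(m = m, miss = miss)
  }
  bres <- gw(msk_b); rres <- gw(msk_r)

  out <- data.table::data.table(
    id = gmap$id, trial = gmap$trial,
    prop_raw_missing = prop_raw_missing,
    prop_onscreen_visual = prop_onscreen_visual,
    occ_central_presound = occ_central_presound,
    central_prop_previsual = central_prop_previsual,
    bad_prop_post1 = bad_prop_post1,
    bad_prop_post2 = bad_prop_post2,
    latency_s = latency_s,
    first_aoi = first_aoi)
  out <- cbind(out, aoi_time)
  out[, `:=`(baseline_mm = bres$m,
             prop_missing_baseline = bres$miss,
             response_mm = rres$m,
             prop_missing_response = rres$miss)]
  out[, dilation_mm := pupil_dilation(baseline_mm, response_mm)]
  out[, pupil_fallback := seq_len(.N) %in% om$fallback]

  # category occupying the first-entered AOI position
  cats <- design_config()$categories
  poscols <- paste0("pos_", cats)
  if (all(poscols %in% names(evj))) {
    posm <- as.matrix(evj[, poscols, with = FALSE])
    hit <- posm == out$first_aoi
    whichcat <- max.col(replace(hit, is.na(hit), FALSE), ties.method = "first")
    anyhit <- rowSums(hit, na.rm = TRUE) > 0
    out[, first_aoi_category := ifelse(anyhit, cats[whichcat], NA_character_)]
    out[, first_look_face := ifelse(is.na(first_aoi_category), NA_integer_,
                                    as.integer(first_aoi_category == "face"))]
  }
  out[]
}
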