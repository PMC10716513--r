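# Trial screening: the five rejection criteria, the participant-level
# inclusion rule, and assembly of the analysis-ready trial table.

#' Apply the five trial rejection criteria
#'
#' Flags per trial (TRUE = criterion violated):
#' \describe{
#'   \item{c1}{gaze was not at the central attention-grabbing area for more
#'     than 40% of the 500 ms before sound onset;}
#'   \item{c2}{gaze was not at all within the central area during the 200 ms
#'     before visual onset;}
#'   \item{c3}{gaze missing or outside the screen during the 500 ms after
#'     visual onset (first clause; reading configurable as any sample /
#'     entire window / proportion), or for more than 25% of the subsequent
#'     500 ms;}
#'   \item{c4}{no AOI entry of at least 100 ms during the visual
#'     presentation;}
#'   \item{c5}{latency to first AOI below 200 ms or above 1 s.}
#' }
#' A trial is valid iff no criterion is violated. All five are always
#' evaluated; violations are reported, never raised.
#'
#' @param features per-trial feature table from [preprocess_trials()].
#' @param config pipeline configuration.
#' @return `data.table` with `id`, `trial`, `c1`..`c5`, `valid`,
#'   `reject_reason` (first violated criterion or `NA`).
#' @export
apply_trial_criteria <- function(features, config = pipeline_config()) {
  f <- data.table::as.data.table(features)
  c1 <- f$occ_central_presound <= config$c1_occupancy
  c2 <- f$central_prop_previsual == 0
  first_clause <- switch(config$c3_mode,
    any = f$bad_prop_post1 > 0,
    all = f$bad_prop_post1 >= 1,
    proportion = f$bad_prop_post1 > config$c3_prop,
    stop("c3_mode must be one of 'any', 'all', 'proportion'"))
  c3 <- first_clause | f$bad_prop_post2 > config$c3_prop
  c4 <- is.na(f$latency_s)
  lv <- config$latency_valid_s
  c5 <- !is.na(f$latency_s) & (f$latency_s < lv[1] | f$latency_s > lv[2])
  flags <- data.table::data.table(id = f$id, trial = f$trial,
                                  c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5)
  flags[, valid := !(c1 | c2 | c3 | c4 | c5)]
  cm <- as.matrix(flags[, c("c1", "c2", "c3", "c4", "c5")])
  firstv <- apply(cm, 1L, function(r) which(r)[1L])
  flags[, reject_reason := ifelse(valid, NA_character_,
                                  paste0("c", firstv))]
  flags[]
}

#' Participant-level inclusion rule
#'
#' A participant is included iff at least `threshold` (default 70%) of their
#' trials are valid; "below 70%" excludes.
#'
#' @param flags per-trial validity flags from [apply_trial_criteria()].
#' @param threshold inclusion threshold on the valid-trial fraction.
#' @return `data.table` with per-infant `n_trials`, `n_valid`, `frac_valid`,
#'   `included`.
#' @export
include_participant <- function(flags, threshold = 0.70) {
  f <- data.table::as.data.table(flags)
  s <- f[, list(n_trials = .N, n_valid = sum(valid)), by = "id"]
  s[, frac_valid := n_valid / n_trials]
  s[, included := frac_valid >= threshold]
  s[]
}

#' Assemble the analysis-ready trial table
#'
#' Joins features, validity flags, trial events and participant metadata;
#' keeps valid trials of included participants; codes the first-look-face
#' indicator (1 iff the first qualifying look landed on the face image);
#' adds the number of valid trials per participant and standardised dilation
#' and baseline columns.
#'
#' @param features per-trial features from [preprocess_trials()].
#' @param flags validity flags from [apply_trial_criteria()].
#' @param events trial event table.
#' @param participants per-infant table (`id`, `age`, `sex`).
#' @param config pipeline configuration (`dilation_standardize`: `"global"`
#'   z-scores across all analysed trials, `"per_infant"` within infant).
#' @return One-row-per-valid-trial `data.frame` with factor-coded design
#'   columns, outcomes and data-quality covariates.
#' @export
assemble_trial_table <- function(features, flags, events, participants,
                                 config = pipeline_config()) {
  f <- data.table::as.data.table(features)
  fl <- data.table::as.data.table(flags)
  ev <- data.table::copy(data.table::as.data.table(events))
  if (!"trial" %in% names(ev)) ev[, trial := trial_index]
  pt <- data.table::as.data.table(participants)
  if (!all(f$id %in% pt$id) || !all(f$id %in% ev$id)) {
    stop("assemble_trial_table: infant ids in features are missing from ",
         "events or participants")
  }
  x <- merge(f, fl[, c("id", "trial", "valid")], by = c("id", "trial"))
  evcols <- intersect(c("id", "trial", "block", "pair_index", "order_in_pair",
                        "sound_id", "content", "volume", "isi_s"), names(ev))
  x <- merge(x, ev[, evcols, with = FALSE], by = c("id", "trial"))
  if (nrow(x) != nrow(f)) stop("assemble_trial_table: id/trial mismatch")
  x <- merge(x, pt, by = "id")
  inc <- include_participant(fl, config$include_threshold)
  x <- merge(x, inc[, c("id", "n_valid", "included")], by = "id")
  x <- x[valid & included == TRUE]

  ages <- unique(pt$age)
  ages <- ages[order(as.numeric(gsub("\\D", "", ages)))]
  out <- data.frame(
    id = factor(x$id),
    age = factor(x$age, levels = ages),
    sex = factor(x$sex),
    content = factor(x$content, levels = c("silent", "social", "nonsocial")),
    volume = factor(x$volume, levels = c("none", "low", "high")),
    repetition = factor(x$order_in_pair, levels = c("first", "second")),
    isi_s = x$isi_s,
    trial = x$trial,
    latency_s = x$latency_s,
    first_look_face = x$first_look_face,
    dilation_mm = x$dilation_mm,
    baseline_mm = x$baseline_mm,
    prop_raw_missing = x$prop_raw_missing,
    prop_onscreen_visual = x$prop_onscreen_visual,
    n_valid = x$n_valid
  )
  zsc <- function(v, grp = NULL) {
    if (is.null(grp)) return(as.numeric(scale(v)))
    stats::ave(v, grp, FUN = function(u) {
      s <- stats::sd(u, na.rm = TRUE)
      if (is.na(s) || s == 0) u * 0 else (u - mean(u, na.rm = TRUE)) / s
    })
  }
  if (config$dilation_standardize == "per_infant") {
    out$dilation_z <- zsc(out$dilation_mm, out$id)
    out$baseline_z <- zsc(out$baseline_mm, out$id)
  } else {
    out$dilation_z <- zsc(out$dilation_mm)
    out$baseline_z <- zsc(out$baseline_mm)
  }
  out
}
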