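# Readers / writers for the long-format sample TSV and trial event TSV, and
# the end-to-end pipeline driver. Missing values are the explicit token "NA";
# times are seconds, gaze in screen-centred visual degrees, pupil in mm.

sample_schema_ <- c("id", "trial", "t", "lx", "ly", "rx", "ry", "lp", "rp")

#' Write / read the long-format sample table
#'
#' One row per sample. Columns may appear in any order in the file; the
#' header is authoritative. On reading, rows are ordered by id, trial, time,
#' and strictly increasing time within trial is enforced (the offending row
#' is named).
#'
#' @param samples sample table.
#' @param path file path.
#' @return `read_samples()` returns a `data.table` in canonical column
#'   order.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA")
  missing_cols <- setdiff(sample_schema_, names(dt))
  if (length(missing_cols)) {
    stop("sample file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(sample_schema_, c("id", "trial"))) {
    if (!is.numeric(dt[[col]])) {
      bad <- which(!is.na(dt[[col]]) &
                     is.na(suppressWarnings(as.numeric(dt[[col]]))))[1]
      stop("non-numeric value in column '", col, "' (data row ",
           if (is.na(bad)) "?" else bad, ")")
    }
  }
  dt <- dt[, sample_schema_, with = FALSE]
  data.table::setorderv(dt, c("id", "trial", "t"))
  g <- data.table::rleid(dt$id, dt$trial)
  same <- g[-1L] == g[-length(g)]
  if (any(same & diff(dt$t) <= 0)) {
    bad <- which(same & diff(dt$t) <= 0)[1L] + 1L
    stop("non-monotone time within trial at data row ", bad)
  }
  dt
}

#' Write / read the trial event table
#'
#' One row per trial with condition labels, onset markers and image
#' positions.
#' @param events event table.
#' @param path file path.
#' @return `read_events()` returns a `data.table`.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = "NA")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, preprocesses every trial, applies the
#' rejection criteria and the participant inclusion rule, assembles the
#' analysis table, and optionally fits the standard model set (volume on
#' dilation, age on latency, age on face selection). Deterministic given the
#' seeds in the arguments; a structured log records trials rejected per
#' criterion and participants excluded.
#'
#' @param config pipeline configuration from [pipeline_config()].
#' @param simulate if `TRUE`, generate the cohort with [simulate_cohort()];
#'   otherwise read `samples.tsv`, `events.tsv`, `participants.tsv` from
#'   `input_dir`.
#' @param seed cohort simulation seed.
#' @param params simulation parameters (when simulating).
#' @param input_dir input directory (when not simulating).
#' @param out_dir optional output directory for TSV artifacts.
#' @param fit_models fit the standard model set.
#' @return List with `features`, `flags`, `inclusion`, `table`, `fits`
#'   (when requested), `log`, and the simulated `cohort` (when simulating).
#' @export
run_pipeline <- function(config = pipeline_config(), simulate = TRUE,
                         seed = 1, params = sim_params(), input_dir = NULL,
                         out_dir = NULL, fit_models = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (simulate) {
    cohort <- stage("simulate", simulate_cohort(params, seed))
    samples <- cohort$samples
    events <- cohort$events
    participants <- cohort$participants
  } else {
    cohort <- NULL
    samples <- stage("read", read_samples(file.path(input_dir, "samples.tsv")))
    events <- stage("read", read_events(file.path(input_dir, "events.tsv")))
    participants <- stage("read", data.table::fread(
      file.path(input_dir, "participants.tsv")))
  }
  features <- stage("preprocess", preprocess_trials(samples, events, config))
  flags <- stage("qc", apply_trial_criteria(features, config))
  inclusion <- stage("qc", include_participant(flags,
                                               config$include_threshold))
  table <- stage("assemble",
                 assemble_trial_table(features, flags, events, participants,
                                      config))
  log <- list(
    n_trials = nrow(flags),
    rejected_per_criterion = vapply(paste0("c", 1:5),
                                    function(cn) sum(flags[[cn]]),
                                    integer(1)),
    n_valid_trials = sum(flags$valid),
    n_participants = nrow(inclusion),
    participants_excluded = sum(!inclusion$included),
    n_analysis_rows = nrow(table))
  fits <- NULL
  if (fit_models) {
    fits <- stage("models", list(
      dilation_volume = fit_mixed(dilation_mm ~ volume + repetition + age +
                                    (1 | id), table),
      latency_age = fit_mixed(latency_s ~ age + (1 | id), table),
      face_age = fit_mixed(first_look_face ~ age + (1 | id), table,
                           family = "binomial")))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_samples(samples, file.path(out_dir, "samples.tsv"))
    write_events(events, file.path(out_dir, "events.tsv"))
    utils::write.table(features, file.path(out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(flags, file.path(out_dir, "flags.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(table, file.path(out_dir, "analysis_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(cohort = cohort, features = features, flags = flags,
       inclusion = inclusion, table = table, fits = fits, log = log)
}
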