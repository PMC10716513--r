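#' Default experiment design configuration
#'
#' Describes the paired-trial, two-block audiovisual pop-out design: 6 social
#' and 6 non-social sounds, each presented as one trial pair per block with
#' volumes swapped between blocks, plus two silent trial pairs per block
#' (56 trials in total). Four image categories are shown per trial at the
#' four corners of a cross-like array, each image midpoint 12 degrees
#' horizontally and 6 degrees vertically from the monitor midpoint.
#'
#' @param isi_range_s inter-stimulus interval range (sound onset to visual
#'   array onset), seconds; drawn uniformly per trial.
#' @param images_per_category size of the image pool per category; every
#'   image is used exactly once across the 56 trials.
#' @param sound_duration_range_s range of non-silent sound durations, seconds.
#' @return A list with the design constants used by [generate_schedule()].
#' @export
design_config <- function(isi_range_s = c(0.08, 0.40),
                          images_per_category = 56,
                          sound_duration_range_s = c(0.506, 0.989)) {
  list(
    n_social = 6L,
    n_nonsocial = 6L,
    n_silent_pairs_per_block = 2L,
    volumes = c("low", "high"),
    categories = c("face", "manmade", "natural", "shape"),
    # position codes 1..4 = SW, SE, NW, NE corners of the array
    positions = data.frame(
      pos = 1:4,
      label = c("SW", "SE", "NW", "NE"),
      x = c(-12, 12, -12, 12),
      y = c(-6, -6, 6, 6)
    ),
    isi_range_s = isi_range_s,
    images_per_category = as.integer(images_per_category),
    sound_duration_range_s = sound_duration_range_s
  )
}

#' Assign image positions with the no-consecutive-repeat constraint
#'
#' Draws, for each trial, a random bijection of the four image categories onto
#' the four array positions, such that no category occupies the same position
#' on two consecutive trials. Uses per-trial rejection sampling (a valid
#' derangement relative to the previous trial always exists for 4 positions).
#'
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param n_trials number of trials.
#' @param categories character vector of category names (length 4).
#' @param max_retries rejection-sampling bound per trial; exceeding it is a
#'   bug signal and raises an error.
#' @return Integer matrix `n_trials x 4` of position codes (1..4), columns
#'   named by category.
#' @export
assign_positions <- function(seed = NULL, n_trials, categories, max_retries = 1000L) {
  k <- length(categories)
  with_seed_(seed, {
    out <- matrix(NA_integer_, nrow = n_trials, ncol = k,
                  dimnames = list(NULL, categories))
    prev <- NULL
    for (i in seq_len(n_trials)) {
      tries <- 0L
      repeat {
        perm <- sample.int(k)
        if (is.null(prev) || !any(perm == prev)) break
        tries <- tries + 1L
        if (tries > max_retries) {
          stop("assign_positions: constraint satisfaction failed after ",
               max_retries, " retries")
        }
      }
      out[i, ] <- perm
      prev <- perm
    }
    out
  })
}

#' Generate a counterbalanced trial schedule
#'
#' Builds one participant's 56-trial schedule: trials come in pairs sharing
#' sound and volume; pairs are arranged in two 14-pair blocks with the same
#' sound sequence but volumes swapped between blocks; two silent pairs per
#' block; every image appears exactly once; image categories never repeat a
#' position on consecutive trials. Volume assignment within a block is
#' balanced within content category (3 high + 3 low per content).
#'
#' @param seed integer seed; schedules are deterministic given the seed.
#' @param design design configuration from [design_config()].
#' @return An object of class `trial_schedule`: a list with `trials` (one row
#'   per trial), `sounds` (the sound inventory) and `seed`.
#' @export
generate_schedule <- function(seed, design = design_config()) {
  if (design$images_per_category < 56L) {
    stop("image pool must contain at least 56 images per category")
  }
  with_seed_(seed, {
    sounds <- data.frame(
      sound_id = c(sprintf("soc%d", seq_len(design$n_social)),
                   sprintf("non%d", seq_len(design$n_nonsocial))),
      content = rep(c("social", "nonsocial"),
                    c(design$n_social, design$n_nonsocial)),
      duration_s = stats::runif(design$n_social + design$n_nonsocial,
                                design$sound_duration_range_s[1],
                                design$sound_duration_range_s[2]),
      stringsAsFactors = FALSE
    )
    sounds <- rbind(sounds, data.frame(sound_id = "silence", content = "silent",
                                       duration_s = 0))

    # volume of each sound in block A, balanced within content (block B swaps)
    vol_a <- c(sample(rep(design$volumes, length.out = design$n_social)),
               sample(rep(design$volumes, length.out = design$n_nonsocial)))
    names(vol_a) <- sounds$sound_id[sounds$content != "silent"]

    # pair sequence: 12 sound pairs shuffled, 2 silent pairs interleaved at
    # random slots; the same sequence is used in both blocks
    sound_seq <- sample(names(vol_a))
    n_pairs <- length(sound_seq) + design$n_silent_pairs_per_block
    silent_slots <- sort(sample.int(n_pairs, design$n_silent_pairs_per_block))
    seq_ids <- character(n_pairs)
    seq_ids[silent_slots] <- "silence"
    seq_ids[-silent_slots] <- sound_seq

    blocks <- lapply(c(A = "A", B = "B"), function(b) {
      volmap <- if (b == "A") vol_a else
        stats::setNames(ifelse(vol_a == "high", "low", "high"), names(vol_a))
      vol <- ifelse(seq_ids == "silence", "none", unname(volmap[seq_ids]))
      data.frame(block = b, sound_id = seq_ids, volume = vol,
                 stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, blocks)
    pairs$pair_index <- seq_len(nrow(pairs))

    trials <- pairs[rep(seq_len(nrow(pairs)), each = 2L), ]
    trials$order_in_pair <- rep(c("first", "second"), nrow(pairs))
    trials$trial_index <- seq_len(nrow(trials))
    trials$content <- sounds$content[match(trials$sound_id, sounds$sound_id)]
    trials$sound_duration_s <-
      sounds$duration_s[match(trials$sound_id, sounds$sound_id)]
    trials$isi_s <- stats::runif(nrow(trials), design$isi_range_s[1],
                                 design$isi_range_s[2])

    # image assignment: each of the 56 per-category images exactly once
    for (cat in design$categories) {
      ord <- sample.int(design$images_per_category)[seq_len(nrow(trials))]
      trials[[paste0("image_", cat)]] <- sprintf("%s_%02d", cat, ord)
    }
    pos <- assign_positions(NULL, nrow(trials), design$categories)
    for (cat in design$categories) {
      trials[[paste0("pos_", cat)]] <- pos[, cat]
    }
    rownames(trials) <- NULL
    trials <- trials[, c("trial_index", "block", "pair_index", "order_in_pair",
                         "sound_id", "content", "volume", "sound_duration_s",
                         "isi_s",
                         paste0("image_", design$categories),
                         paste0("pos_", design$categories))]
    structure(list(trials = trials, sounds = sounds, seed = seed,
                   design = design),
              class = "trial_schedule")
  })
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat("Trial schedule:", nrow(x$trials), "trials,",
      sum(x$trials$content == "silent"), "silent, seed", x$seed, "\n")
  invisible(x)
}

#' Validate a trial schedule against the design invariants
#'
#' Checks every structural invariant of the paired two-block design and
#' returns the names of violated invariants (empty if the schedule is valid).
#' Violations are reported, never raised.
#'
#' @param schedule a `trial_schedule` or a bare data frame of trials.
#' @param design design configuration.
#' @return Character vector of violated invariant names.
#' @export
validate_schedule <- function(schedule, design = design_config()) {
  tr <- if (inherits(schedule, "trial_schedule")) schedule$trials else schedule
  bad <- character(0)
  note <- function(name) bad <<- c(bad, name)

  if (nrow(tr) != 56L) note("trial_count")
  cc <- table(factor(tr$content, c("social", "nonsocial", "silent")))
  if (cc[["social"]] != 24L || cc[["nonsocial"]] != 24L) note("content_count")
  if (cc[["silent"]] != 8L) note("silent_count")
  vol <- table(factor(tr$volume[tr$content != "silent"], c("low", "high")))
  if (vol[["low"]] != 24L || vol[["high"]] != 24L) note("volume_count")
  if (!all(tr$volume[tr$content == "silent"] == "none") ||
      any(tr$volume[tr$content != "silent"] == "none")) note("silent_volume")
  if (!all(table(tr$block) == 28L) || length(unique(tr$block)) != 2L) {
    note("block_size")
  }
  if (any(tr$isi_s < design$isi_range_s[1] - 1e-12 |
          tr$isi_s > design$isi_range_s[2] + 1e-12)) note("isi_range")

  # pair symmetry: both trials of a pair share sound and volume
  sp <- split(tr, tr$pair_index)
  pair_ok <- vapply(sp, function(p) {
    nrow(p) == 2L && length(unique(p$sound_id)) == 1L &&
      length(unique(p$volume)) == 1L &&
      identical(sort(p$order_in_pair), c("first", "second"))
  }, logical(1))
  if (!all(pair_ok)) note("pair_symmetry")

  # within-block volume balance (12 high + 12 low sound trials per block)
  ns0 <- tr[tr$content != "silent", ]
  bb <- table(ns0$block, ns0$volume)
  if (!all(bb == 12L)) note("block_volume_balance")

  # cross-block volume swap for non-silent sounds
  ns <- tr[tr$content != "silent", ]
  a <- sort(paste(ns$sound_id[ns$block == "A"], ns$volume[ns$block == "A"]))
  swap <- ifelse(ns$volume[ns$block == "B"] == "high", "low", "high")
  b <- sort(paste(ns$sound_id[ns$block == "B"], swap))
  if (!identical(a, b)) note("volume_swap")

  imgcols <- grep("^image_", names(tr), value = TRUE)
  imgs <- unlist(tr[imgcols], use.names = FALSE)
  if (anyDuplicated(imgs) || length(imgs) != 4L * nrow(tr)) {
    note("image_uniqueness")
  }

  poscols <- grep("^pos_", names(tr), value = TRUE)
  pos <- as.matrix(tr[poscols])
  if (any(apply(pos, 1, anyDuplicated) > 0)) note("position_bijection")
  if (nrow(pos) > 1L && any(pos[-1L, , drop = FALSE] ==
                            pos[-nrow(pos), , drop = FALSE])) {
    note("position_consecutive_repeat")
  }
  bad
}

#' Write / read a schedule as TSV
#'
#' One row per trial; the sound inventory is reconstructed from the trial
#' rows on reading.
#' @param schedule a `trial_schedule`.
#' @param path file path.
#' @return `read_schedule()` returns a `trial_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(schedule$trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  sounds <- unique(tr[, c("sound_id", "content", "sound_duration_s")])
  names(sounds)[3] <- "duration_s"
  rownames(sounds) <- NULL
  structure(list(trials = tr, sounds = sounds, seed = NA_integer_,
                 design = design_config()),
            class = "trial_schedule")
}
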