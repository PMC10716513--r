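# Vectorised signal primitives. Every function here operates on flat sample
# vectors with an optional block-contiguous group id `g` (one block per
# trial), so the same code path serves a single trial and a whole cohort.
# Nothing ever leaks across a group boundary. Callers that apply several
# primitives to the same grid can precompute the group bounds once and pass
# them as `gb`.

# index of most recent valid sample at or before each position (0 if none)
prev_valid_ <- function(v) {
  iv <- seq_along(v)
  iv[!v] <- 0L
  cummax(iv)
}

# index of next valid sample at or after each position (n + 1 if none)
next_valid_ <- function(v) {
  n <- length(v)
  iv <- seq_len(n)
  iv[!rev(v)] <- 0L
  rev((n + 1L) - cummax(iv))
}

# Linear interpolation over short gaps of missing samples. A gap is the run
# of NA between two valid samples of the same group; its duration is the time
# from the last valid sample to the next valid sample, and only gaps strictly
# shorter than `max_gap_s` are filled. Leading/trailing gaps have no flank and
# are never filled.
gap_fill_ <- function(x, t, g = NULL, max_gap_s = 0.150, gb = NULL) {
  n <- length(x)
  if (n == 0L) return(x)
  v <- !is.na(x)
  if (all(v) || !any(v)) return(x)
  if (is.null(gb)) gb <- group_bounds_(g, n)
  p <- prev_valid_(v)
  nx <- next_valid_(v)
  idx <- which(!v & p >= gb$start & nx <= gb$end)
  if (length(idx)) {
    idx <- idx[(t[nx[idx]] - t[p[idx]]) < max_gap_s]
  }
  if (length(idx)) {
    lo <- p[idx]; hi <- nx[idx]
    w <- (t[idx] - t[lo]) / (t[hi] - t[lo])
    x[idx] <- x[lo] + (x[hi] - x[lo]) * w
  }
  x
}

# Centered moving average over valid samples; missing samples stay missing and
# are simply excluded from neighbouring windows. Edges use the truncated
# window. `halfwidth` is in samples (window = 2*halfwidth + 1 samples).
moving_avg_ <- function(x, g = NULL, halfwidth, gb = NULL) {
  n <- length(x)
  if (n == 0L || halfwidth <= 0L) return(x)
  v <- !is.na(x)
  if (is.null(gb)) gb <- group_bounds_(g, n)
  x0 <- x
  x0[!v] <- 0
  cs <- c(0, cumsum(x0))
  cn <- c(0, cumsum(as.numeric(v)))
  i <- seq_len(n)
  lo <- pmax(i - halfwidth, gb$start)
  hi <- pmin(i + halfwidth, gb$end)
  s <- cs[hi + 1L] - cs[lo]
  m <- cn[hi + 1L] - cn[lo]
  out <- s / m
  out[m == 0] <- NA_real_
  out[!v] <- NA_real_
  out
}

# Binocular pupil mean with dynamic offset reconstruction. Where both eyes are
# valid the output is their plain mean and the offset d = L - R is observed;
# where one eye is missing, the offset is linearly interpolated (nearest-edge
# extrapolated at group edges) from surrounding both-valid samples and the
# available eye is shifted by half the reconstructed offset. Groups with no
# both-valid sample fall back to the plain available-eye mean and are flagged.
offset_mean_ <- function(left, right, t, g = NULL, gb = NULL) {
  n <- length(left)
  lv <- !is.na(left); rv <- !is.na(right)
  bv <- lv & rv
  d <- left - right  # NA unless both valid
  if (is.null(gb)) gb <- group_bounds_(g, n)
  p <- prev_valid_(bv)
  nx <- next_valid_(bv)
  hasp <- p >= gb$start
  hasn <- nx <= gb$end
  dhat <- d
  i2 <- which(!bv & hasp & hasn)
  if (length(i2)) {
    lo <- p[i2]; hi <- nx[i2]
    w <- (t[i2] - t[lo]) / (t[hi] - t[lo])
    dhat[i2] <- d[lo] + (d[hi] - d[lo]) * w
  }
  i1 <- which(!bv & hasp & !hasn)
  dhat[i1] <- d[p[i1]]
  i0 <- which(!bv & !hasp & hasn)
  dhat[i0] <- d[nx[i0]]
  none <- !bv & !hasp & !hasn
  dhat[none] <- 0  # fallback: plain available-eye mean
  out <- (left + right) / 2
  lonly <- lv & !rv
  ronly <- rv & !lv
  out[lonly] <- left[lonly] - dhat[lonly] / 2
  out[ronly] <- right[ronly] + dhat[ronly] / 2
  fallback <- if (is.null(g)) {
    any(none & (lv | rv))
  } else {
    unique(g[none & (lv | rv)])
  }
  list(pupil = out, fallback = fallback)
}

# Recode samples outside an absolute range to missing.
recode_range_ <- function(x, range) {
  x[!is.na(x) & (x < range[1] | x > range[2])] <- NA_real_
  x
}

# Recode samples more than k SD from their group mean to missing. Mean/SD are
# computed once per group on the input (after any range recoding).
recode_sd_ <- function(x, g = NULL, k = 3) {
  n <- length(x)
  if (is.null(g)) g <- rep.int(1L, n)
  dt <- data.table::data.table(x = x, g = g)
  st <- dt[, list(m = mean(x, na.rm = TRUE), s = stats::sd(x, na.rm = TRUE)),
           by = "g"]
  pos <- match(g, st$g)
  m <- st$m[pos]; s <- st$s[pos]
  bad <- !is.na(x) & !is.na(s) & s > 0 & abs(x - m) > k * s
  x[bad] <- NA_real_
  x
}

# Moving-average halfwidth in samples for a window length in ms at rate fs.
ma_halfwidth_ <- function(window_ms, fs) {
  as.integer(floor(window_ms / 1000 * fs / 2 + 1e-9))
}

# Minimum run length in samples for a dwell duration in ms at rate fs
# (run duration = sample count x nominal period).
dwell_samples_ <- function(min_dwell_ms, fs) {
  as.integer(ceiling(min_dwell_ms / 1000 * fs - 1e-9))
}
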