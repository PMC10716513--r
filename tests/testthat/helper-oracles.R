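# Independent brute-force oracles. These deliberately use naive loops and
# stats::approx rather than the package's vectorised code paths.

oracle_gap_fill <- function(x, t, max_gap_s = 0.150) {
  n <- length(x)
  out <- x
  i <- 1L
  while (i <= n) {
    if (is.na(x[i])) {
      j <- i
      while (j <= n && is.na(x[j])) j <- j + 1L
      if (i > 1L && j <= n && (t[j] - t[i - 1L]) < max_gap_s) {
        for (k in i:(j - 1L)) {
          out[k] <- stats::approx(c(t[i - 1L], t[j]), c(x[i - 1L], x[j]),
                                  xout = t[k])$y
        }
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  out
}

oracle_movavg <- function(x, halfwidth) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    w <- x[max(1L, i - halfwidth):min(n, i + halfwidth)]
    out[i] <- mean(w, na.rm = TRUE)
  }
  out
}

oracle_aoi <- function(x, y, centers, half) {
  n <- length(x)
  out <- matrix(0L, n, nrow(centers))
  for (i in seq_len(n)) {
    if (is.na(x[i]) || is.na(y[i])) next
    for (j in seq_len(nrow(centers))) {
      if (x[i] >= centers$x[j] - half && x[i] <= centers$x[j] + half &&
          y[i] >= centers$y[j] - half && y[i] <= centers$y[j] + half) {
        out[i, j] <- 1L
        break
      }
    }
  }
  colnames(out) <- centers$pos
  out
}

# first run of >= need consecutive samples in any AOI; returns onset time
# and AOI id (codes: 0 none, 1..4 AOIs)
oracle_first_entry <- function(code, t, visual_onset, need) {
  n <- length(code)
  i <- 1L
  while (i <= n) {
    if (code[i] > 0L) {
      j <- i
      while (j <= n && code[j] == code[i]) j <- j + 1L
      if (j - i >= need) {
        return(list(latency_s = t[i] - visual_onset, aoi = code[i]))
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  list(latency_s = NA_real_, aoi = NA_integer_)
}

oracle_recode <- function(x, range_mm = c(1.5, 9), sd_k = 3, mask = NULL) {
  out <- x
  out[!is.na(out) & (out < range_mm[1] | out > range_mm[2])] <- NA
  m <- mean(out, na.rm = TRUE)
  s <- stats::sd(out, na.rm = TRUE)
  if (!is.na(s) && s > 0) {
    out[!is.na(out) & abs(out - m) > sd_k * s] <- NA
  }
  if (!is.null(mask)) out[mask] <- NA
  out
}
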