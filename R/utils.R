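# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` uses the current stream.
with_seed_ <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Per-sample start/end global indices of contiguous groups. `g` must be
# block-contiguous (all samples of a trial adjacent), as produced by the
# readers and the simulator.
group_bounds_ <- function(g, n) {
  if (is.null(g)) {
    return(list(start = rep.int(1L, n), end = rep.int(n, n)))
  }
  r <- rle(as.vector(g))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  list(start = rep.int(starts, r$lengths), end = rep.int(ends, r$lengths))
}

stop_if_nonmonotone_ <- function(t, g = NULL) {
  n <- length(t)
  if (n < 2L) return(invisible(TRUE))
  same <- if (is.null(g)) rep.int(TRUE, n - 1L) else g[-1L] == g[-n]
  if (any(same & diff(t) <= 0)) {
    bad <- which(same & diff(t) <= 0)[1L] + 1L
    stop("timestamps must be strictly increasing within a trial (row ", bad, ")")
  }
  invisible(TRUE)
}

# Nominal sampling interval of a time grid.
sample_period_ <- function(t) {
  if (length(t) < 2L) return(NA_real_)
  stats::median(diff(t))
}
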