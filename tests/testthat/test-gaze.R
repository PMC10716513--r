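test_that("gap interpolation fills short gaps exactly and leaves long ones", {
  fs <- 600
  t <- (0:299) / fs
  # no missing samples: identity
  s <- flat_series(300)
  expect_identical(interpolate_gaze(s), s)

  # 100 ms gap on a linear ramp: filled values equal the ramp exactly
  x <- t
  x[100:159] <- NA  # 60 samples = 100 ms
  filled <- gap_fill_(x, t)
  expect_equal(filled, t, tolerance = 1e-12)

  # 200 ms gap stays missing
  x2 <- t
  x2[100:219] <- NA  # 120 samples = 200 ms
  expect_identical(gap_fill_(x2, t), x2)

  # leading and trailing gaps are never filled
  x3 <- t
  x3[1:5] <- NA
  x3[296:300] <- NA
  out <- gap_fill_(x3, t)
  expect_true(all(is.na(out[1:5])) && all(is.na(out[296:300])))
})

test_that("gap interpolation matches the brute-force oracle and is idempotent", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(30:120, 1)
    t <- cumsum(runif(n, 1 / 700, 1 / 500))
    x <- cumsum(rnorm(n))
    x[runif(n) < 0.35] <- NA
    got <- gap_fill_(x, t)
    expect_equal(got, oracle_gap_fill(x, t), tolerance = 1e-12)
    expect_equal(gap_fill_(got, t), got, tolerance = 1e-12)  # idempotent
    # filled values lie within the flanking sample range
    filled <- is.na(x) & !is.na(got)
    if (any(filled)) {
      expect_true(all(got[filled] >= min(x, na.rm = TRUE) - 1e-12 &
                        got[filled] <= max(x, na.rm = TRUE) + 1e-12))
    }
  }
})

test_that("gap interpolation never crosses trial boundaries", {
  t <- rep((0:9) / 600, 2)
  g <- rep(1:2, each = 10)
  x <- rnorm(20)
  x[9:12] <- NA  # spans the boundary
  out <- gap_fill_(x, t, g)
  expect_true(all(is.na(out[9:12])))
})

test_that("interpolate_gaze raises on non-monotone time", {
  s <- flat_series(10)
  s$t[5] <- s$t[3]
  expect_error(interpolate_gaze(s), "strictly increasing")
})

test_that("binocular averaging takes the mean of available eyes", {
  s <- flat_series(3)
  s$lx <- c(1, NA, NA); s$rx <- c(3, 3, NA)
  s$ly <- c(0, 0, NA); s$ry <- c(0, NA, NA)
  cyc <- average_eyes(s)
  expect_equal(cyc$x, c(2, 3, NA))
  expect_equal(cyc$y, c(0, 0, NA))

  # random series: elementwise nan-aware mean oracle
  set.seed(7)
  s2 <- flat_series(200)
  for (ch in c("lx", "ly", "rx", "ry")) {
    v <- rnorm(200)
    v[runif(200) < 0.3] <- NA
    s2[[ch]] <- v
  }
  cyc2 <- average_eyes(s2)
  exp_x <- apply(cbind(s2$lx, s2$rx), 1,
                 function(r) if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE))
  expect_equal(cyc2$x, exp_x)
})

test_that("AOI indicators implement closed 11-degree squares", {
  aois <- aoi_set()
  g <- data.frame(t = 1:5 / 600,
                  x = c(12, 0, 12 - 5.5, 12 + 5.51, NA),
                  y = c(6, 0, 6 + 5.5, 6, 1))
  ind <- aoi_vectors(g, aois)
  expect_equal(unname(ind[1, ]), c(0L, 0L, 0L, 1L))  # NE centre
  expect_equal(sum(ind[2, ]), 0L)                    # screen centre
  expect_equal(unname(ind[3, "4"]), 1L)              # boundary is inside
  expect_equal(sum(ind[4, ]), 0L)                    # just outside
  expect_equal(sum(ind[5, ]), 0L)                    # missing codes as 0

  # geometric oracle on random points
  set.seed(11)
  g2 <- data.frame(t = (1:1000) / 600,
                   x = runif(1000, -25, 25), y = runif(1000, -15, 15))
  expect_identical(unname(aoi_vectors(g2, aois)),
                   unname(oracle_aoi(g2$x, g2$y, aois$centers, aois$half)))
  expect_true(all(rowSums(aoi_vectors(g2, aois)) <= 1))  # disjoint AOIs
})

test_that("first-entry latency requires a 100 ms dwell", {
  fs <- 600
  n <- 1200
  t <- (0:(n - 1)) / fs
  vo <- 0.5
  code <- integer(n)
  # single 150 ms run starting 300 ms post-onset -> latency 0.300
  i0 <- which(t >= vo + 0.3)[1]
  code[i0:(i0 + 89)] <- 2L
  r <- first_entry_latency(code, t, vo, fs = fs)
  expect_equal(r$latency_s, 0.300, tolerance = 1.01 / fs)
  expect_equal(r$aoi, 2L)

  # 80 ms run at 250 ms then 200 ms run at 500 ms -> the first is too short
  code2 <- integer(n)
  i1 <- which(t >= vo + 0.25)[1]
  code2[i1:(i1 + 47)] <- 1L  # 48 samples = 80 ms
  i2 <- which(t >= vo + 0.5)[1]
  code2[i2:(i2 + 119)] <- 3L
  r2 <- first_entry_latency(code2, t, vo, fs = fs)
  expect_equal(r2$latency_s, 0.500, tolerance = 1.01 / fs)
  expect_equal(r2$aoi, 3L)

  # no qualifying entry: absent
  r3 <- first_entry_latency(integer(n), t, vo, fs = fs)
  expect_true(is.na(r3$latency_s) && is.na(r3$aoi))

  # latency is invariant to samples outside the visual window
  code4 <- code
  code4[t < vo] <- 4L
  r4 <- first_entry_latency(code4, t, vo, fs = fs)
  expect_equal(r4$latency_s, r$latency_s)
})

test_that("first-entry latency matches the run-length scan oracle", {
  set.seed(21)
  fs <- 600
  for (rep in 1:60) {
    n <- sample(100:500, 1)
    t <- (0:(n - 1)) / fs
    code <- sample(0:4, n, replace = TRUE, prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
    # stretch some runs so qualifying entries exist occasionally
    r <- first_entry_latency(code, t, 0, fs = fs)
    o <- oracle_first_entry(code, t, 0, dwell_samples_(100, fs))
    expect_equal(r$latency_s, o$latency_s)
    expect_equal(r$aoi, o$aoi)
  }
})

test_that("missingness statistics count raw gaps and on-screen fractions", {
  s <- flat_series(600)   # 1 s at 600 Hz
  ms <- missingness_stats(s, interpolate_gaze(s), 0.2, 0.8)
  expect_equal(ms$prop_raw_missing, 0)
  expect_equal(ms$prop_onscreen_visual, 1)

  # half the samples missing in both eyes
  s2 <- s
  for (ch in c("lx", "ly", "rx", "ry")) s2[[ch]][1:300] <- NA
  ms2 <- missingness_stats(s2, s2, 0.2, 0.8)
  expect_equal(ms2$prop_raw_missing, 0.5)

  # 30% of the visual window off-screen -> on-screen 0.7
  s3 <- s
  vis <- s3$t >= 0.2 & s3$t < 0.8
  offs <- which(vis)[1:round(0.3 * sum(vis))]
  s3$lx[offs] <- 30; s3$rx[offs] <- 30
  ms3 <- missingness_stats(s3, s3, 0.2, 0.8)
  expect_equal(ms3$prop_onscreen_visual, 0.7, tolerance = 1e-6)
})
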