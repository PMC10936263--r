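test_that("read_recording round-trips a signal CSV and checks its shape", {
  fs <- 1926
  n <- 2 * fs
  set.seed(11)
  cm <- small_map()
  rec <- emg_recording(
    list(anterior_deltoid_left = rnorm(n), anterior_deltoid_right = rnorm(n)),
    fs = fs, channel_map = cm
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path, channel_map = cm, fs = fs)
  expect_length(back$samples, 2L)
  expect_length(back$samples[[1]], n)
  expect_equal(back$samples$anterior_deltoid_left,
               rec$samples$anterior_deltoid_left, tolerance = 1e-6)
  # fs inferred from the time column when not supplied
  inferred <- read_recording(path, channel_map = cm)
  expect_equal(inferred$fs, fs, tolerance = 1e-6)
})

test_that("read_recording rejects degenerate and incomplete files", {
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_recording(empty, small_map()), "parse error|no data")

  # only the left channel present: error names the missing channel
  partial <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,anterior_deltoid_left", "0,0.1", "0.001,0.2"),
             partial)
  expect_error(read_recording(partial, small_map(), fs = 1000),
               "anterior_deltoid_right")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,anterior_deltoid_left,anterior_deltoid_right",
               "0,0.1,0.3", "0.001,oops,0.4"), bad)
  expect_error(read_recording(bad, small_map(), fs = 1000),
               "non-numeric.*row 2")
})

test_that("remove_spikes leaves clean signals alone and repairs isolated spikes", {
  set.seed(21)
  x <- band_limited_noise(20000, 1926)
  clean <- remove_spikes(x)
  expect_identical(clean$samples, x)
  expect_length(clean$replaced, 0L)

  # one sample at 50x the robust scale: exactly that index is replaced,
  # and the exhaustive scan over all samples finds no other excursion
  scale <- mad(abs(x))
  y <- x
  y[7000] <- 50 * scale
  out <- remove_spikes(y)
  over <- which(abs(y) > out$threshold &
                  abs(y) > 3 * pmax(abs(c(y[-1], 0)), abs(c(0, y[-length(y)]))))
  expect_identical(out$replaced, 7000L)
  expect_true(all(over %in% out$replaced))
  expect_gte(out$samples[7000], min(y[6999], y[7001]))
  expect_lte(out$samples[7000], max(y[6999], y[7001]))

  expect_warning(res <- remove_spikes(rep(0, 500)), "zero robust scale")
  expect_identical(res$samples, rep(0, 500))
  expect_length(res$replaced, 0L)
})

test_that("remove_spikes is idempotent on spiked fixtures", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- band_limited_noise(5000, 1926)
    idx <- sample(200:4800, 3)
    x[idx] <- 40 * mad(abs(x)) * sign(rnorm(3))
    once <- remove_spikes(x)
    twice <- remove_spikes(once$samples)
    expect_identical(twice$samples, once$samples)
    expect_length(twice$replaced, 0L)
  }
})

test_that("bandpass kills DC, passes mid-band tones with zero lag", {
  fs <- 1926
  # DC: frequency-response oracle at 0 Hz, and the filtered constant
  bt <- signal::butter(1, c(20, 450) / (fs / 2), type = "pass")
  expect_lt(filter_gain(bt, 0, fs), 1e-6)
  dc <- rep(1, 4 * fs)
  y <- bandpass(dc, fs)
  mid <- y[fs:(3 * fs)]
  expect_lt(max(abs(mid)), 0.01)

  # 100 Hz tone: oracle gain ~ 1, measured amplitude within 1%, lag 0
  g <- filter_gain(bt, 100, fs)^2  # forward-backward squares |H|
  expect_equal(g, 1, tolerance = 0.01)
  t <- (0:(6 * fs - 1)) / fs
  x <- sin(2 * pi * 100 * t)
  y <- bandpass(x, fs)
  core <- (fs):(5 * fs)
  expect_equal(max(abs(y[core])), 1, tolerance = 0.01)
  lags <- -5:5
  cc <- vapply(lags, function(l) {
    i <- core
    stats::cor(x[i], y[i + l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0L)

  expect_identical(bandpass(rep(0, 1000), fs), rep(0, 1000))
  expect_error(bandpass(x, fs, f_hi = fs / 2), "Nyquist")
})

test_that("zero-lag holds across the passband", {
  fs <- 1926
  t <- (0:(4 * fs - 1)) / fs
  for (f in c(50, 150, 300)) {
    x <- sin(2 * pi * f * t)
    y <- bandpass(x, fs)
    core <- fs:(3 * fs)
    cc <- vapply(-3:3, function(l) stats::cor(x[core], y[core + l]),
                 numeric(1))
    expect_equal((-3:3)[which.max(cc)], 0L)
  }
})

test_that("rectify is elementwise absolute value", {
  expect_identical(rectify(c(-1, 2, -3)), c(1, 2, 3))
  expect_identical(rectify(rep(0, 5)), rep(0, 5))
  set.seed(3)
  x <- rnorm(100)
  expect_identical(rectify(x), rectify(-x))
})

test_that("envelope has unity DC gain, tracks |sin| mean, stays non-negative", {
  fs <- 1926
  const <- rep(0.7, 6 * fs)
  env <- envelope(const, fs)
  expect_equal(mean(env[(2 * fs):(4 * fs)]), 0.7, tolerance = 0.01)

  t <- (0:(8 * fs - 1)) / fs
  r <- rectify(sin(2 * pi * 100 * t))
  env <- envelope(r, fs)
  plateau <- env[(3 * fs):(5 * fs)]
  expect_equal(mean(plateau), 2 / pi, tolerance = 0.02)

  expect_identical(envelope(rep(0, 1000), fs), rep(0, 1000))

  set.seed(4)
  for (i in 1:5) {
    x <- rectify(band_limited_noise(8000, fs) * runif(1, 0.1, 10))
    expect_true(all(envelope(x, fs) >= 0))
  }
})

test_that("mvic_reference finds the highest windowed mean", {
  fs <- 1000
  expect_equal(mvic_reference(rep(0.5, 5 * fs), fs), 0.5)

  ramp <- seq(0, 1, length.out = 5 * fs)
  expect_equal(mvic_reference(ramp, fs), 0.9, tolerance = 1e-3)

  two <- c(rep(0.3, 2 * fs), rep(0, fs), rep(0.8, 2 * fs))
  expect_equal(mvic_reference(two, fs), 0.8)

  expect_error(mvic_reference(rep(1, 100), fs), "shorter")
})

test_that("interval_series blocks, normalizes and discards partial tails", {
  s <- interval_series(c(1, 1, 1, 1, 3, 3, 3, 3), fs = 4, mvic = 10)
  expect_equal(s$values, c(10, 30))
  expect_equal(s$n_intervals, 2L)

  s9 <- interval_series(rep(1, 9), fs = 4, mvic = 10)
  expect_equal(s9$n_intervals, 2L)

  expect_error(interval_series(rep(1, 8), fs = 4, mvic = 0),
               "normalization")

  # length = floor(duration) for arbitrary durations
  set.seed(5)
  for (i in 1:10) {
    fs <- sample(c(500, 1000, 1926), 1)
    dur <- runif(1, 1, 6)
    n <- floor(fs * dur)
    s <- interval_series(runif(n), fs = fs, mvic = 1)
    expect_equal(s$n_intervals, n %/% fs)
    expect_true(all(s$values >= 0))
  }
})

test_that("the full envelope chain recovers a known plateau", {
  rec <- recover_deltoid(seed = 99)
  vals <- rec$series$values[!rec$series$edge]
  active <- vals[vals > 5]
  expect_equal(mean(active), 40, tolerance = 0.1)
})
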