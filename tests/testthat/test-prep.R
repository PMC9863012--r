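test_that("band-pass removes DC, passes the band, attenuates per design", {
  fs <- 10
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  # constant gravity only -> output ~ 0 after settling
  rec <- raw_recording(numeric(length(t)), numeric(length(t)),
                       rep(1, length(t)), fs, T0)
  sig <- bandpass_filter(rec)
  core <- seq(200, length(t) - 200)
  expect_lt(max(abs(sig$z[core])), 1e-6)

  # in-band 1 Hz sinusoid keeps its amplitude within 5%
  x <- 0.1 * sin(2 * pi * 1 * t)
  rec <- raw_recording(x, numeric(length(t)), rep(1, length(t)), fs, T0)
  sig <- bandpass_filter(rec)
  expect_equal(max(abs(sig$x[core])), 0.1, tolerance = 0.05)

  # 5 Hz at 20 Hz sampling: attenuation at least the design's single-pass
  # magnitude response (zero-phase application squares it)
  fs2 <- 20
  t2 <- seq(0, 60 - 1 / fs2, by = 1 / fs2)
  x2 <- 0.1 * sin(2 * pi * 5 * t2)
  rec2 <- raw_recording(x2, numeric(length(t2)), rep(1, length(t2)), fs2, T0)
  sig2 <- bandpass_filter(rec2)
  bf <- signal::butter(4, c(0.25, 2.5) / (fs2 / 2), type = "pass")
  ew <- exp(-1i * 2 * pi * 5 / fs2 * (seq_along(bf$b) - 1))
  H5 <- abs(sum(bf$b * ew) / sum(bf$a * ew))
  core2 <- seq(150, length(t2) - 150)
  expect_lt(max(abs(sig2$x[core2])), 0.1 * H5)
  expect_error(bandpass_filter(raw_recording(0, 0, 0, 4, T0)), "Nyquist")
})

test_that("ZCM counts upward crossings per axis summed into epochs", {
  fs <- 10
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  sig <- make_signal(0.1 * sin(2 * pi * 1 * t), fs = fs)
  ep <- zcm_epochs(sig)
  expect_equal(ep$counts, 60)          # one upward crossing per cycle

  expect_equal(zcm_epochs(make_signal(numeric(1200)))$counts, c(0, 0))
  const <- make_signal(rep(0.04, 1200), rep(0.04, 1200), rep(0.04, 1200))
  expect_equal(zcm_epochs(const)$counts, c(0, 0))

  # sub-threshold signal stays at zero after adding a constant below the gap
  sub <- 0.02 * sin(2 * pi * 1.3 * t)
  expect_equal(zcm_epochs(make_signal(sub + 0.02))$counts, 0)
})

test_that("ZCM equals the brute-force per-sample crossing counter", {
  set.seed(42)
  for (i in 1:100) {
    fs <- sample(c(5, 10, 20), 1)
    n <- fs * sample(120:240, 1)
    off_s <- sample(0:59, 1)
    sig <- make_signal(rnorm(n, 0, 0.06), rnorm(n, 0, 0.06),
                       rnorm(n, 0, 0.06), fs = fs, start = T0 + off_s)
    expect_equal(zcm_epochs(sig)$counts, brute_zcm(sig))
  }
})

test_that("epoch grid is anchored to the next whole minute", {
  fs <- 10
  sig <- make_signal(rnorm(fs * 150, 0, 0.06), fs = fs, start = T0 + 30)
  ep <- zcm_epochs(sig)
  expect_equal(as.numeric(ep$start_time) %% 60, 0)
  expect_equal(length(ep$counts), 2)   # 150 s - 30 s offset -> 2 whole epochs
})

test_that("sliding-window smoothing averages 5+5 with truncated edges", {
  x <- rep(7, 40)
  expect_equal(smooth_epochs(make_epochs(x))$counts, x)
  imp <- rep(0, 40); imp[20] <- 11
  sm <- smooth_epochs(make_epochs(imp))
  expect_equal(sm$counts[15:25], rep(1, 11))
  expect_equal(sm$counts[14], 0)
  y <- c(3, 9, 6, 1, 8, 2, 5, 4, 7, 10, 11, 0)
  sm2 <- smooth_epochs(make_epochs(y))
  expect_equal(sm2$counts[1], mean(y[1:6]))          # truncated left window
  expect_equal(sm2$counts[12], mean(y[7:12]))        # truncated right window
  expect_equal(sm2$counts[7], mean(y[2:12]))         # full 11-epoch window
  # mean conservation within 1% on a day-long series
  long <- rpois(1440, 30)
  expect_equal(mean(smooth_epochs(make_epochs(long))$counts), mean(long),
               tolerance = 0.01)
})

test_that("validity rule is an inclusive 2-day bound", {
  expect_false(validity_filter(make_epochs(rep(1, 47 * 60)))$accepted)
  expect_true(validity_filter(make_epochs(rep(1, 49 * 60)))$accepted)
  expect_true(validity_filter(make_epochs(rep(1, 48 * 60)))$accepted)
  # recordings are trimmed to whole minutes
  rec <- raw_recording(rnorm(650), rnorm(650), rnorm(650), 10, T0)
  v <- validity_filter(rec)
  expect_equal(v$x$n_samples, 600)
  expect_false(v$accepted)
})
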