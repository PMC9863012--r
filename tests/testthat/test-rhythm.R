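test_that("M10/L5/RA/ADAT match block profiles and constants", {
  day <- rep(0, 1440)
  day[(8 * 60 + 1):(18 * 60)] <- 100     # active 08:00-18:00
  ep <- make_epochs(rep(day, 2))
  p <- nonparametric_profile(ep)
  expect_equal(p$M10, 100)
  expect_equal(p$L5, 0)
  expect_equal(p$RA, 1)
  expect_equal(p$ADAT, 100 * 600)

  p2 <- nonparametric_profile(make_epochs(rep(50, 1440)))
  expect_equal(p2$M10, 50)
  expect_equal(p2$L5, 50)
  expect_equal(p2$RA, 0)
  expect_equal(p2$ADAT, 50 * 1440)
})

test_that("M10/L5 equal exhaustive circular window search", {
  set.seed(7)
  days <- matrix(rpois(2 * 1440, rep(20 * (1 + sin(2 * pi * (1:1440) / 1440)),
                                     2)), nrow = 2, byrow = TRUE)
  ep <- make_epochs(as.vector(t(days)))
  p <- nonparametric_profile(ep)
  o10 <- apply(days, 1, function(d) brute_window_stats(d, 600)["max"])
  o5 <- apply(days, 1, function(d) brute_window_stats(d, 300)["min"])
  expect_equal(p$M10, mean(o10))
  expect_equal(p$L5, mean(o5))
})

test_that("IS is 1 for a repeated daily pattern and ~1/days for noise", {
  pat <- rep(seq(2, 48, by = 2), each = 60)           # nonconstant 24-h pattern
  expect_equal(interdaily_stability(make_epochs(rep(pat, 5))), 1)
  expect_error(interdaily_stability(make_epochs(rep(3, 2 * 1440))),
               "degenerate")

  set.seed(1)
  vals <- replicate(1000, is_stat(matrix(rnorm(240), 10, 24)))
  expect_lt(abs(mean(vals) - 1 / 10), 0.005)
  # binning consistency: wrapper equals the statistic on manual hourly bins
  set.seed(2)
  x <- rpois(2 * 1440, 20)
  manual <- matrix(colMeans(matrix(x, nrow = 60)), ncol = 24, byrow = TRUE)
  expect_equal(interdaily_stability(make_epochs(x)), is_stat(manual))
})

test_that("IV matches the white-noise and sinusoid closed forms", {
  set.seed(3)
  vals <- replicate(1000, iv_stat(rnorm(240)))
  expect_equal(mean(vals), 2, tolerance = 0.05)

  h <- 0:(240 - 1)
  iv_cos <- iv_stat(cos(2 * pi * h / 24))
  expect_equal(iv_cos, 2 * (1 - cos(2 * pi / 24)), tolerance = 0.005)
  expect_error(iv_stat(rep(1, 48)), "degenerate")
})

test_that("IS and IV are affine-invariant; IV is reversal-invariant", {
  set.seed(4)
  x <- rpois(2 * 1440, 15) + rep(rep(c(5, 30), each = 720), 2)
  ep <- make_epochs(x)
  ep_scaled <- make_epochs(3.7 * x + 11)
  expect_equal(interdaily_stability(ep), interdaily_stability(ep_scaled))
  expect_equal(intradaily_variability(ep), intradaily_variability(ep_scaled))
  h <- rnorm(100)
  expect_equal(iv_stat(h), iv_stat(rev(h)))
})

test_that("clock thirds and daily summaries follow the window definitions", {
  td <- thirds_and_daily(make_epochs(rep(10, 1440)))
  expect_equal(unname(unlist(td[1:3])), c(10, 10, 10))
  expect_equal(td$daily_activity_stdev, 0)

  day <- rep(0, 1440); day[(16 * 60 + 1):1440] <- 30
  td2 <- thirds_and_daily(make_epochs(day))
  expect_equal(td2[["3_thrd"]], 30)
  expect_equal(td2[["1_thrd"]], 0)
  expect_equal(td2[["2_thrd"]], 0)
  expect_equal(td2$daily_activity_mean, 10)

  td3 <- thirds_and_daily(make_epochs(c(rep(10, 1440), rep(20, 1440))))
  expect_equal(unname(unlist(td3[1:3])), c(15, 15, 15))
})

test_that("Savitzky-Golay boundary features recover sinusoid envelopes", {
  idx <- 1:(3 * 1440)
  ep <- make_epochs(50 + 20 * sin(2 * pi * idx / 1440))
  b <- savgol_boundary_features(ep)
  expect_equal(b$avg_ceiling_value, 70, tolerance = 0.05 * 70)
  expect_equal(b$avg_floor_value, 30, tolerance = 0.05 * 30)
  expect_equal(b$avg_ceiling_floor_diff, 40, tolerance = 0.05 * 40)
  expect_equal(b$e_v_avg_value, 50, tolerance = 0.02 * 50)

  # single ceiling point -> population sd of a singleton is 0
  bump <- 10 + seq(0, 5, length.out = 300); bump[150] <- bump[150] + 60
  b2 <- savgol_boundary_features(make_epochs(bump))
  expect_equal(b2$std_upper, 0)
  expect_error(savgol_boundary_features(make_epochs(seq_len(300))),
               "degenerate")
})
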