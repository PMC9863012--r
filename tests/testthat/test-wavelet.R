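test_that("sleep concatenation keeps nights in time order", {
  ep <- make_epochs(rpois(5 * 600, 2))
  per <- data.frame(night_index = 1:5,
                    start_epoch = c(1, 601, 1201, 1801, 2401),
                    end_epoch = c(481, 1081, 1681, 2281, 2881),
                    duration_minutes = 480)
  expect_length(concatenate_sleep(ep, per, nights = 5), 5 * 480)
  expect_warning(s3 <- concatenate_sleep(ep, per[1:3, ], nights = 5),
                 "only 3")
  expect_length(s3, 3 * 480)
  expect_error(concatenate_sleep(ep, per[1, , drop = FALSE]), "at least 2")
})

test_that("Morlet CWT matches a direct-convolution oracle", {
  set.seed(11)
  x <- rnorm(64)
  periods <- 4:10   # near-Nyquist periods differ by discretization
  m <- morlet_cwt(x, periods)
  expect_equal(m$coefficients, brute_morlet(x, periods), tolerance = 1e-6)
})

test_that("CWT is linear, zero on zero input, and peaks at the period", {
  expect_true(all(morlet_cwt(rep(0, 600), 1:100)$coefficients == 0))
  set.seed(12)
  x <- rnorm(512)
  m1 <- morlet_cwt(x, 1:100)
  m3 <- morlet_cwt(3 * x, 1:100)
  expect_equal(m3$coefficients, 3 * m1$coefficients, tolerance = 1e-10)

  t <- 1:600
  sine <- sin(2 * pi * t / 60)
  curve <- structure_curve(morlet_cwt(sine, 1:200))
  peak_scale <- curve$scales[which.max(curve$values)]
  expect_lt(abs(peak_scale - 60) / 60, 0.10)
})

test_that("structure curve equals brute-force summation and scales as c^2", {
  set.seed(13)
  x <- rnorm(256)
  m <- morlet_cwt(x, 5:40)
  curve <- structure_curve(m)
  brute <- vapply(seq_along(m$scales), function(i) {
    tot <- 0
    for (tt in seq_len(ncol(m$coefficients)))
      tot <- tot + m$coefficients[i, tt]^2
    tot
  }, numeric(1))
  expect_equal(curve$values, brute)
  m2 <- morlet_cwt(2 * x, 5:40)
  expect_equal(structure_curve(m2)$values, 4 * curve$values,
               tolerance = 1e-10)
})

test_that("band scalars integrate and summarize the stated scale windows", {
  flat <- structure(list(scales = 1:200,
                         values = ifelse(1:200 >= 20 & 1:200 <= 100, 3, 0)),
                    class = "structure_curve")
  b <- structure_band_features(flat)
  expect_equal(b$structure_pm, 80 * 3)
  expect_equal(b$structure_pm_stdev, 0)
  zero <- structure(list(scales = 1:200, values = rep(0, 200)),
                    class = "structure_curve")
  expect_equal(structure_band_features(zero)$structure_pm, 0)
  short <- structure(list(scales = 1:50, values = rep(1, 50)),
                     class = "structure_curve")
  expect_error(structure_band_features(short), "outside")
})

test_that("periodic structure concentrates in-band energy above noise", {
  set.seed(14)
  t <- 1:480
  pm <- function(x) {
    structure_band_features(structure_curve(
      morlet_cwt(x, 1:200)))$structure_pm
  }
  diffs <- replicate(20, {
    noise <- rnorm(480)
    sine <- sqrt(2) * sin(2 * pi * t / 60 + runif(1, 0, 2 * pi))
    pm(sine) - pm(noise)
  })
  expect_gt(median(diffs), 0)
})
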