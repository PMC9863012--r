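test_that("baseline features are mean, population sd and zero fraction", {
  b <- baseline_features(list(s1 = make_epochs(rep(5, 20)),
                              s2 = make_epochs(c(0, 0, 10, 10)),
                              s3 = make_epochs(rep(0, 8))))
  expect_equal(unname(b["s1", ]), c(5, 0, 0))
  expect_equal(unname(b["s2", ]), c(5, 5, 0.5))
  expect_equal(unname(b["s3", ]), c(0, 0, 1))
  expect_error(baseline_features(list(make_epochs(numeric(0)))), "empty")
})

test_that("pooled confusion metrics match the printed definitions", {
  truth <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 8), 0, 0, rep(0, 7), 1, 1, 1)
  m <- compute_metrics(pred, truth)
  expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(8, 7, 3, 2))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 8 / 11, tolerance = 1e-12)
  expect_equal(m$recall, 0.8)
})

test_that("a perfectly separable feature is classified perfectly", {
  set.seed(30)
  X <- matrix(c(rnorm(12, -4, 0.2), rnorm(12, 4, 0.2)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c("C", "CTF"), each = 12)
  for (alg in c("lgr", "rf", "gb")) {
    r <- cross_validate(alg, X, y, positive = "CTF", folds = 10, seed = 4)
    expect_equal(r$accuracy, 1.0)
  }
})

test_that("metrics recompute identically from stored predictions", {
  set.seed(31)
  X <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("C", "PSF"), each = 20)
  r <- cross_validate("lgr", X, y, positive = "PSF", folds = 10, seed = 9)
  m2 <- compute_metrics(r$predicted, r$truth)
  expect_equal(r$accuracy, m2$accuracy)
  expect_equal(r$precision, m2$precision)
  expect_equal(r$recall, m2$recall)
  expect_length(r$prob, 40)
})

test_that("label-shuffled data scores at chance level", {
  set.seed(32)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("f", 1:3)))
  accs <- vapply(1:50, function(i) {
    y <- sample(rep(c("C", "CTF"), each = 15))
    cross_validate("lgr", X, y, positive = "CTF", folds = 10,
                   seed = i)$accuracy
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)
})

test_that("the search enumerates algorithm x task x combination", {
  set.seed(33)
  m <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(sprintf("s%02d", 1:30),
                              feature_registry()[1:12]))
  tab <- feature_table(m, rownames(m),
                       rep(c("C", "CTF", "PSF"), each = 10))
  tasks <- make_tasks(tab$group_label)
  expect_named(tasks, c("C_vs_CTF", "C_vs_PSF"))
  combos <- list(colnames(m)[1:4], colnames(m)[5:8])

  dry <- run_search(tab, tasks, combos, algorithms = c("lgr", "rf", "gb"),
                    dry_run = TRUE)
  expect_equal(dry$n_planned, 3 * 2 * 2)

  one <- run_search(tab, tasks["C_vs_CTF"], combos[1], algorithms = "lgr",
                    folds = 5, seed = 2)
  expect_length(one$results, 1)
  expect_equal(one$results[[1]]$task, "C_vs_CTF")
  empty <- run_search(tab, tasks, list(), algorithms = "lgr")
  expect_length(empty$results, 0)
})

test_that("baseline retention keeps strictly better models only", {
  mk <- function(acc, alg = "lgr", task = "C_vs_CTF")
    structure(list(algorithm = alg, task = task, accuracy = acc),
              class = "model_result")
  baselines <- list(`C_vs_CTF.lgr` = mk(0.68))
  kept <- filter_above_baseline(list(mk(0.70), mk(0.68), mk(0.60)), baselines)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$accuracy, 0.70)
  expect_true(all(vapply(kept, `[[`, numeric(1), "accuracy") > 0.68))
  expect_error(filter_above_baseline(list(mk(0.7, task = "C_vs_PSF")),
                                     baselines), "missing baseline")
})
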