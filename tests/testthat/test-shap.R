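test_that("a constant model attributes nothing", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(letters[1:10], c("u", "v")))
  model <- fit_classifier("majority", X, rep(c(0, 1), 5))
  s <- shapley_values(model, X)
  expect_true(all(s$values == 0))
  expect_equal(s$base_value, 0.5)
})

test_that("exact enumeration matches the linear closed form", {
  set.seed(41)
  X <- matrix(rnorm(15 * 4), 15, 4,
              dimnames = list(sprintf("s%02d", 1:15), paste0("f", 1:4)))
  coef <- c(f1 = 0.8, f2 = -1.2, f3 = 0.25, f4 = 0)
  model <- fixed_linear_model(coef, intercept = 0.3)
  s <- shapley_values(model, X, background_max = Inf)
  expect_equal(s$method, "exact")
  expect_equal(s$values, linear_shap(coef, X, X), tolerance = 1e-10)
  # local accuracy: attributions + base value = model output
  expect_equal(unname(rowSums(s$values)) + s$base_value, unname(s$fx),
               tolerance = 1e-10)
  expect_equal(unname(s$fx), as.numeric(0.3 + X %*% coef))
})

test_that("local accuracy holds exactly for tree models too", {
  set.seed(42)
  X <- matrix(rnorm(20 * 5), 20, 5,
              dimnames = list(sprintf("s%02d", 1:20), paste0("f", 1:5)))
  y <- as.integer(X[, 1] + X[, 2] > 0)
  model <- fit_classifier("gb", X, y, seed = 7)
  s <- shapley_values(model, X, background_max = Inf)
  expect_equal(unname(rowSums(s$values)) + s$base_value,
               unname(predict_prob(model, X)), tolerance = 1e-6)
})

test_that("the sampling estimator agrees with exact enumeration", {
  set.seed(43)
  X <- matrix(rnorm(12 * 5), 12, 5,
              dimnames = list(sprintf("s%02d", 1:12), paste0("f", 1:5)))
  coef <- setNames(c(1, -0.5, 0.7, 0.2, -1), paste0("f", 1:5))
  model <- fixed_linear_model(coef)
  ex <- shapley_values(model, X, exact_max = 8, background_max = Inf)
  # force the permutation estimator; for an additive model every
  # permutation yields the same marginal contributions
  sm <- shapley_values(model, X, exact_max = 2, n_perm = 8,
                       background_max = Inf, seed = 5)
  expect_equal(sm$method, "sampling")
  expect_equal(sm$values, ex$values, tolerance = 1e-8)
  expect_equal(unname(rowSums(sm$values)) + sm$base_value,
               unname(sm$fx), tolerance = 1e-8)
})

test_that("symmetric features receive equal attributions", {
  set.seed(44)
  x1 <- rnorm(15)
  X <- cbind(a = x1, b = x1)                 # identical columns
  rownames(X) <- sprintf("s%02d", 1:15)
  model <- fixed_linear_model(c(a = 0.6, b = 0.6))
  s <- shapley_values(model, X, background_max = Inf)
  expect_equal(s$values[, "a"], s$values[, "b"], tolerance = 1e-10)
})

test_that("aggregation is element-wise, linear and order-invariant", {
  subj <- sprintf("s%02d", 1:6)
  m1 <- matrix(rnorm(12), 6, 2, dimnames = list(subj, c("zero_ratio", "IS")))
  m2 <- -m1[, "zero_ratio", drop = FALSE]
  agg <- aggregate_attributions(list(m1, m2))
  expect_equal(unname(agg[, "zero_ratio"]), rep(0, 6))  # opposite values cancel
  expect_equal(agg[, "IS"], m1[, "IS"])
  expect_equal(aggregate_attributions(list(m1)), m1)
  k3 <- aggregate_attributions(list(m1, m1, m1))
  expect_equal(k3, 3 * m1)
  expect_equal(aggregate_attributions(list(m2, m1)),
               aggregate_attributions(list(m1, m2))[, c("zero_ratio", "IS")])
  bad <- m1; rownames(bad) <- rev(subj)
  expect_error(aggregate_attributions(list(m1, bad)), "mismatch")
})

test_that("rankings order by mean |attribution| with correlation signs", {
  subj <- sprintf("s%02d", 1:20)
  set.seed(45)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(subj, c("L5", "IS", "IV")))
  agg <- cbind(L5 = 2 * X[, "L5"], IS = -0.5 * X[, "IS"],
               IV = rep(0, 20))
  rk <- rank_features(agg, X)
  expect_equal(rk$feature, c("L5", "IS", "IV"))
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$direction[rk$feature == "L5"], "+")
  expect_equal(rk$direction[rk$feature == "IS"], "-")
  expect_equal(rk$direction[rk$feature == "IV"], "?")
})
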