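reg2tab <- function(m, labels = rep("C", nrow(m))) {
  colnames(m) <- feature_registry()[seq_len(ncol(m))]
  feature_table(m, sprintf("s%02d", seq_len(nrow(m))), labels)
}

test_that("standard normalization centers, scales and is idempotent", {
  tab <- reg2tab(cbind(c(1, 2, 3), c(5, 5, 5)))
  nm <- standard_normalize(tab)
  m <- feature_matrix(nm)
  expect_equal(mean(m[, 1]), 0)
  expect_equal(actiphen:::pop_sd(m[, 1]), 1)
  expect_equal(m[, 2], c(s01 = 0, s02 = 0, s03 = 0))
  expect_equal(attr(nm, "constant_columns"), colnames(m)[2])
  nm2 <- standard_normalize(nm)
  expect_equal(feature_matrix(nm2), m)
})

test_that("Welch screen matches the textbook statistic and edge rules", {
  m <- cbind(a = c(1:5, 11:15), b = rep(1:5, 2))
  labels <- rep(c("CTF", "C"), each = 5)
  # a: means 3 vs 13, equal variances 2.5 -> t = 10, df = 8
  kept <- welch_filter(m, labels, positive = "CTF", alpha = 0.3)
  p <- attr(kept, "p_values")
  expect_equal(unname(p["a"]), 2 * pt(-10, df = 8))
  expect_true("a" %in% kept)

  # literally identical class samples -> p = 1, dropped
  expect_false("b" %in% kept)
  expect_equal(unname(p["b"]), 1)

  # zero variance both classes: dropped when means equal, kept otherwise
  m2 <- cbind(a = rep(c(0, 1), each = 4), b = rep(2, 8))
  l2 <- rep(c("CTF", "C"), each = 4)
  k2 <- welch_filter(m2, l2, "CTF", alpha = 0.3)
  expect_length(k2, 1)
  expect_true("a" %in% k2)
  expect_equal(attr(k2, "degenerate"), c("a", "b"))
  # monotone in alpha (continuous data, so no p-value sits exactly at 1)
  set.seed(24)
  mc <- cbind(a = c(1:5, 11:15) + rnorm(10, 0, 0.01), b = rnorm(10))
  expect_length(welch_filter(mc, labels, "CTF", alpha = 1.0), 2)
  expect_length(welch_filter(mc, labels, "CTF", alpha = 1e-12), 0)
  expect_error(welch_filter(m[1:6, ], c("CTF", rep("C", 5)), "CTF"),
               "at least two")
})

test_that("the low-correlation graph keeps edges up to the threshold", {
  set.seed(21)
  n <- 40
  x <- as.numeric(scale(rnorm(n)))
  e <- residuals(lm(rnorm(n) ~ x)); e <- as.numeric(scale(e))
  y <- 0.5 * x + sqrt(1 - 0.25) * e        # cor(x, y) = 0.5 exactly
  z <- rnorm(n)
  m <- cbind(f1 = x, f2 = y, f3 = z)
  r12 <- abs(cor(x, y))
  # at threshold exactly |r|: "exceeded" is strict, so the edge stays
  g_eq <- build_low_correlation_graph(m, threshold = r12)
  expect_true(igraph::are_adjacent(g_eq, "f1", "f2"))
  g_below <- build_low_correlation_graph(m, threshold = r12 - 1e-9)
  expect_false(igraph::are_adjacent(g_below, "f1", "f2"))

  # identical columns never connect; independent noise usually does
  m2 <- cbind(f1 = x, f2 = x, f3 = z)
  g2 <- build_low_correlation_graph(m2, threshold = 0.3)
  expect_false(igraph::are_adjacent(g2, "f1", "f2"))
  set.seed(22)
  m3 <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("a", "b")))
  g3 <- build_low_correlation_graph(m3, threshold = 0.3)
  expect_true(igraph::are_adjacent(g3, "a", "b"))
})

test_that("maximal cliques >= min size match exhaustive enumeration", {
  gr_from_adj <- function(adj) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- paste0("v", seq_len(nrow(adj)))
    g
  }
  adj8 <- matrix(TRUE, 8, 8); diag(adj8) <- FALSE
  cl <- enumerate_cliques(gr_from_adj(adj8), 8)
  expect_length(cl, 1)
  expect_equal(cl[[1]], paste0("v", 1:8))

  adj10 <- matrix(FALSE, 10, 10)
  adj10[1:8, 1:8] <- TRUE; diag(adj10) <- FALSE
  cl10 <- enumerate_cliques(gr_from_adj(adj10), 8)
  expect_equal(cl10, list(paste0("v", 1:8)))

  adj7 <- matrix(TRUE, 7, 7); diag(adj7) <- FALSE
  expect_length(enumerate_cliques(gr_from_adj(adj7), 8), 0)

  set.seed(23)
  for (i in 1:30) {
    n <- 12
    adj <- matrix(runif(n * n) < 0.55, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    got <- enumerate_cliques(gr_from_adj(adj), 4)
    want <- brute_max_cliques(adj, 4)
    want <- lapply(want, function(idx) sort(paste0("v", idx)))
    want <- want[order(vapply(want, paste, "", collapse = "\r"))]
    expect_equal(got, want)
  }
})

test_that("combination sampling is uniform-without-replacement and seeded", {
  cl <- lapply(1:50, function(i) paste0("f", i + 0:7))
  s1 <- sample_combinations(cl, 10, seed = 3)
  s2 <- sample_combinations(cl, 10, seed = 3)
  expect_identical(s1, s2)
  expect_length(s1, 10)
  expect_false(anyDuplicated(vapply(s1, paste, "", collapse = ",")) > 0)
  expect_warning(all5 <- sample_combinations(cl[1:5], 1600, seed = 1),
                 "only 5")
  expect_length(all5, 5)
})
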