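# Feature-selection funnel: standard normalization, lenient Welch
# screening against control, the low-correlation graph, maximal-clique
# enumeration and random sampling of candidate feature combinations.

#' Standard (z-score) normalization of a feature table
#'
#' Centers each feature column to mean 0 and scales it to population
#' standard deviation 1. Zero-variance columns are left centered and
#' reported in the `constant_columns` attribute.
#'
#' @param table a `feature_table`.
#' @return The normalized `feature_table`.
#' @export
standard_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  m <- feature_matrix(table)
  if (nrow(m) < 2L) stop("need at least two subjects to normalize")
  constant <- character(0)
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[, j]); s <- pop_sd(m[, j])
    m[, j] <- m[, j] - mu
    if (s > 0) m[, j] <- m[, j] / s
    else constant <- c(constant, colnames(m)[j])
  }
  out <- feature_table(m, table$subject_id, table$group_label,
                       attr(table, "registry_version"))
  attr(out, "constant_columns") <- constant
  out
}

#' Welch screen of features against control
#'
#' Per feature, a two-sided Welch unequal-variance t-test between the
#' propensity class and control; features with p below `alpha` (a lenient
#' 0.3 by default) are retained. Degenerate features (zero variance in both
#' classes) are retained only if the class means differ, and flagged.
#'
#' @param table a (normalized) `feature_table`, or a numeric matrix with
#'   named columns.
#' @param labels two-class label vector aligned with the table rows.
#' @param positive label of the propensity class.
#' @param alpha retention threshold on the p-value (strict `p < alpha`).
#' @return Character vector of retained feature names; p-values in the
#'   `p_values` attribute, degenerate columns in `degenerate`.
#' @export
welch_filter <- function(table, labels, positive, alpha = 0.3) {
  m <- if (inherits(table, "feature_table")) feature_matrix(table)
       else as.matrix(table)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L) stop("welch_filter needs exactly two classes")
  a <- m[labels == positive, , drop = FALSE]
  b <- m[labels != positive, , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("each class needs at least two subjects")
  degenerate <- character(0)
  p <- vapply(seq_len(ncol(m)), function(j) {
    x <- a[, j]; y <- b[, j]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      degenerate <<- c(degenerate, colnames(m)[j])
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }, numeric(1))
  names(p) <- colnames(m)
  kept <- colnames(m)[p < alpha]
  attr(kept, "p_values") <- p
  attr(kept, "degenerate") <- degenerate
  kept
}

#' Low-correlation feature graph
#'
#' Nodes are features; an edge is kept iff the absolute pairwise
#' correlation does not exceed `threshold` (edges with |r| strictly above
#' it are deleted), so cliques are sets of mutually weakly-correlated
#' features. Edge weights carry |r|.
#'
#' @param table a `feature_table` (normalized), or numeric matrix.
#' @param features columns to include (default all).
#' @param threshold |r| edge-deletion threshold (default 0.3).
#' @param method correlation method (default `"pearson"`).
#' @return An `igraph` undirected graph with `weight` edge attributes.
#' @export
build_low_correlation_graph <- function(table, features = NULL,
                                        threshold = 0.3,
                                        method = "pearson") {
  m <- if (inherits(table, "feature_table")) feature_matrix(table)
       else as.matrix(table)
  if (!is.null(features)) m <- m[, features, drop = FALSE]
  if (nrow(m) < 3L) stop("need at least three subjects")
  r <- abs(stats::cor(m, method = method))
  r[is.na(r)] <- 1                      # constant columns connect to nothing
  adj <- r <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  el <- igraph::as_edgelist(g)
  igraph::E(g)$weight <- r[cbind(el[, 1], el[, 2])]
  g
}

#' Enumerate maximal cliques of mutually weakly-correlated features
#'
#' All maximal cliques of at least `min_size` members, in deterministic
#' order (lexicographic by sorted member names).
#'
#' @param graph graph from [build_low_correlation_graph()].
#' @param min_size minimum clique size (default 8).
#' @return List of character vectors (sorted feature names).
#' @export
enumerate_cliques <- function(graph, min_size = 8) {
  cl <- igraph::max_cliques(graph, min = min_size)
  cl <- lapply(cl, function(v) sort(igraph::V(graph)$name[v]))
  if (length(cl) == 0L) return(list())
  key <- vapply(cl, paste, character(1), collapse = "\r")
  cl[order(key)]
}

#' Draw random maximal cliques without full enumeration
#'
#' For graphs whose maximal-clique space is too large to enumerate, draws
#' maximal cliques by extending seeded random vertex permutations greedily
#' and deduplicating; every draw is a genuine maximal clique, though the
#' sample is not exactly uniform over the clique space.
#'
#' @param graph graph from [build_low_correlation_graph()].
#' @param n number of cliques wanted.
#' @param min_size minimum clique size.
#' @param seed integer seed.
#' @param attempts maximum greedy draws before giving up.
#' @return List of character vectors (sorted member names).
#' @export
sample_clique_space <- function(graph, n, min_size = 8, seed = 1L,
                                attempts = 60L * n) {
  nm <- igraph::V(graph)$name
  adj <- lapply(igraph::adjacent_vertices(graph, igraph::V(graph)),
                as.integer)
  nv <- length(nm)
  out <- list(); seen <- character(0)
  with_seed(seed, {
    for (a in seq_len(attempts)) {
      if (length(out) >= n) break
      ord <- sample.int(nv)
      cl <- integer(0)
      for (v in ord)
        if (all(cl %in% adj[[v]])) cl <- c(cl, v)
      if (length(cl) < min_size) next
      key <- paste(sort(cl), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- sort(nm[cl])
    }
  })
  out
}

#' Enumerate or sample the clique space, whichever is tractable
#'
#' Counts the maximal cliques first; below `max_enumerable` they are fully
#' enumerated and sampled uniformly, otherwise random maximal cliques are
#' drawn directly.
#'
#' @param graph graph from [build_low_correlation_graph()].
#' @param n combinations wanted.
#' @param min_size minimum clique size.
#' @param seed integer seed.
#' @param max_enumerable enumeration bound on the clique count.
#' @return list(combinations, n_cliques, enumerated).
#' @export
select_combinations <- function(graph, n, min_size = 8, seed = 1L,
                                max_enumerable = 200000) {
  n_cl <- igraph::count_max_cliques(graph, min = min_size)
  if (n_cl <= max_enumerable) {
    cl <- enumerate_cliques(graph, min_size)
    list(combinations = sample_combinations(cl, n, seed),
         n_cliques = n_cl, enumerated = TRUE)
  } else {
    list(combinations = sample_clique_space(graph, n, min_size, seed),
         n_cliques = n_cl, enumerated = FALSE)
  }
}

#' Randomly sample feature combinations
#'
#' Uniform sample without replacement of `n` cliques; if fewer are
#' available, all are returned with a warning. Seed-reproducible.
#'
#' @param cliques list from [enumerate_cliques()].
#' @param n number of combinations (default 1600).
#' @param seed integer seed.
#' @return List of character vectors (the sampled combinations).
#' @export
sample_combinations <- function(cliques, n = 1600, seed = 1L) {
  if (length(cliques) <= n) {
    if (length(cliques) < n)
      warning("only ", length(cliques), " cliques available; requested ", n)
    return(cliques)
  }
  with_seed(seed, cliques[sample.int(length(cliques), n)])
}
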