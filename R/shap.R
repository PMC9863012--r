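# Shapley attribution of model probabilities: exact coalition enumeration
# for small feature sets, a permutation-sampling estimator otherwise, and
# the cross-model row-wise aggregation with direction-annotated rankings.

.popcount <- function(s, k) {
  out <- integer(length(s))
  for (b in 0:(k - 1)) out <- out + (bitwAnd(s, bitwShiftL(1L, b)) > 0L)
  out
}

# v(S) for all subjects and a set of coalitions, by marginal replacement:
# features in S take the subject's values, the rest come from background
# rows; predictions are batched into few large calls for speed.
.coalition_values <- function(model, X, B, masks, k, chunk_rows = 400000L) {
  n <- nrow(X); nb <- nrow(B)
  base <- B[rep(seq_len(nb), times = n), , drop = FALSE]
  xrep <- X[rep(seq_len(n), each = nb), , drop = FALSE]
  block <- nrow(base)
  v <- matrix(0, nrow = length(masks), ncol = n)
  per_chunk <- max(1L, chunk_rows %/% block)
  for (start in seq(1L, length(masks), by = per_chunk)) {
    idx <- start:min(start + per_chunk - 1L, length(masks))
    big <- matrix(0, nrow = block * length(idx), ncol = ncol(X),
                  dimnames = list(NULL, colnames(X)))
    for (ii in seq_along(idx)) {
      m <- base
      sel <- bitwAnd(masks[idx[ii]], bitwShiftL(1L, 0:(k - 1))) > 0L
      if (any(sel)) m[, sel] <- xrep[, sel, drop = FALSE]
      big[((ii - 1) * block + 1):(ii * block), ] <- m
    }
    p <- predict_prob(model, big)
    pm <- matrix(p, nrow = block)
    for (ii in seq_along(idx))
      v[idx[ii], ] <- colMeans(matrix(pm[, ii], nrow = nb))
  }
  v
}

#' Shapley attributions for one fitted model
#'
#' Computes per-subject, per-feature Shapley values of the model's
#' positive-class probability under the marginal-replacement scheme:
#' absent features are replaced by values drawn from background rows (a
#' subsample of the training matrix). Coalitions are enumerated exactly
#' when the model has at most `exact_max` features; otherwise a
#' permutation-sampling estimator with `n_perm` antithetic permutations is
#' used. Both satisfy local accuracy: attributions plus the base value sum
#' to the model output for each subject (exactly for the enumerator, and
#' exactly in the telescoping sense for the permutation estimator).
#'
#' @param model an `acti_model` (or a `model_result`, whose full-data model
#'   is used).
#' @param X training feature matrix (subjects x model features).
#' @param background background rows for replacement (default `X`).
#' @param exact_max feature-count bound for exact enumeration.
#' @param n_perm permutations for the sampling estimator.
#' @param background_max background rows are subsampled to this many.
#' @param seed seed for subsampling and permutations.
#' @return list with `values` (subjects x features matrix), `base_value`
#'   (expected model output over the background), `fx` (per-subject model
#'   output) and `method`.
#' @export
shapley_values <- function(model, X, background = X, exact_max = 8,
                           n_perm = 16, background_max = 8, seed = 1L) {
  if (inherits(model, "model_result")) model <- model$model
  stopifnot(inherits(model, "acti_model"))
  X <- as.matrix(X)[, model$features, drop = FALSE]
  B <- as.matrix(background)[, model$features, drop = FALSE]
  if (nrow(B) > background_max)
    B <- with_seed(seed, B[sample.int(nrow(B), background_max), ,
                           drop = FALSE])
  k <- ncol(X); n <- nrow(X)
  if (k > 30L) stop("too many features for Shapley attribution")
  if (k <= exact_max) {
    masks <- 0:(2^k - 1)
    v <- .coalition_values(model, X, B, masks, k)
    sizes <- .popcount(masks, k)
    wt <- exp(lfactorial(sizes) + lfactorial(k - sizes - 1) - lfactorial(k))
    phi <- matrix(0, nrow = n, ncol = k,
                  dimnames = list(rownames(X), colnames(X)))
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      without <- which(bitwAnd(masks, bit) == 0L)
      with_j <- without + bit               # masks are 0..2^k-1 in order
      phi[, j] <- colSums((v[with_j, , drop = FALSE] -
                           v[without, , drop = FALSE]) * wt[without])
    }
    method <- "exact"
    base <- v[1, 1]
    fx <- v[length(masks), ]
  } else {
    phi <- matrix(0, nrow = n, ncol = k,
                  dimnames = list(rownames(X), colnames(X)))
    perms <- with_seed(seed, {
      half <- lapply(seq_len(ceiling(n_perm / 2)), function(i) sample.int(k))
      c(half, lapply(half, rev))[seq_len(n_perm)]
    })
    v_empty <- .coalition_values(model, X, B, 0L, k)[1, ]
    for (pm in perms) {
      masks <- integer(k)
      mask <- 0L
      for (step in seq_len(k)) {
        mask <- mask + bitwShiftL(1L, pm[step] - 1L)
        masks[step] <- mask
      }
      v <- .coalition_values(model, X, B, masks, k)
      prev <- v_empty
      for (step in seq_len(k)) {
        phi[, pm[step]] <- phi[, pm[step]] + (v[step, ] - prev) / n_perm
        prev <- v[step, ]
      }
    }
    method <- "sampling"
    base <- mean(v_empty)
    fx <- predict_prob(model, X)
  }
  list(values = phi, base_value = base, fx = fx, method = method)
}

#' Row-wise aggregation of attribution matrices across models
#'
#' Element-wise sum of per-subject Shapley values aligned by
#' (subject, feature); features absent from a model contribute zero, so
#' opposite attributions of the same feature in two models cancel.
#'
#' @param shap_list list of results from [shapley_values()] (or bare
#'   attribution matrices with dimnames).
#' @param subjects common subject order (default: taken from the first
#'   matrix; all matrices must agree).
#' @param features feature universe of the aggregate (default: union).
#' @return Subjects x features matrix of summed attributions.
#' @export
aggregate_attributions <- function(shap_list, subjects = NULL,
                                   features = NULL) {
  mats <- lapply(shap_list, function(s)
    if (is.list(s) && !is.null(s$values)) s$values else as.matrix(s))
  if (length(mats) == 0L) stop("nothing to aggregate")
  if (is.null(subjects)) subjects <- rownames(mats[[1]])
  if (is.null(features))
    features <- unique(unlist(lapply(mats, colnames)))
  agg <- matrix(0, nrow = length(subjects), ncol = length(features),
                dimnames = list(subjects, features))
  for (m in mats) {
    if (!identical(rownames(m), subjects))
      stop("subject order mismatch across attribution matrices")
    agg[, colnames(m)] <- agg[, colnames(m)] + m
  }
  agg
}

#' Direction-annotated importance ranking
#'
#' Ranks features by mean absolute aggregated attribution (descending).
#' The direction is the sign of the Pearson correlation between a
#' feature's values and its aggregated attributions: `'+'` when high
#' feature values push decisions toward the propensity class, `'-'` for
#' the opposite, `'?'` when |r| falls below `r_cut` or is undefined.
#'
#' @param agg aggregated attribution matrix from
#'   [aggregate_attributions()].
#' @param X normalized feature matrix with matching subjects (columns may
#'   be a superset).
#' @param r_cut correlation magnitude below which no direction is claimed.
#' @return data.frame `feature`, `rank`, `mean_abs_shap`, `direction`,
#'   `value_corr`, sorted by rank.
#' @export
rank_features <- function(agg, X, r_cut = 0.3) {
  X <- as.matrix(X)
  imp <- colMeans(abs(agg))
  corr <- vapply(colnames(agg), function(f) {
    if (!f %in% colnames(X)) return(NA_real_)
    a <- agg[, f]
    if (stats::sd(a) == 0 || stats::sd(X[, f]) == 0) return(NA_real_)
    stats::cor(X[rownames(agg), f], a)
  }, numeric(1))
  dir <- ifelse(is.na(corr) | abs(corr) < r_cut, "?",
                ifelse(corr > 0, "+", "-"))
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = colnames(agg)[ord], rank = seq_along(ord),
             mean_abs_shap = imp[ord], direction = dir[ord],
             value_corr = corr[ord], row.names = NULL,
             stringsAsFactors = FALSE)
}
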