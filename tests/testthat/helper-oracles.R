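# shared fixtures and independent brute-force oracles

T0 <- as.POSIXct("2023-01-02 00:00:00", tz = "UTC")

make_epochs <- function(values, start = T0, smoothed = TRUE)
  epoch_series(values, start, 60, smoothed = smoothed)

make_signal <- function(x, y = NULL, z = NULL, fs = 10, start = T0) {
  n <- length(x)
  if (is.null(y)) y <- numeric(n)
  if (is.null(z)) z <- numeric(n)
  structure(list(x = x, y = y, z = z,
                 magnitude = sqrt(x^2 + y^2 + z^2),
                 sampling_rate = fs, start_time = start),
            class = "filtered_signal")
}

# sample-by-sample upward-crossing counter, summed over axes per epoch
brute_zcm <- function(sig, tau = 0.05, epoch_seconds = 60) {
  fs <- sig$sampling_rate
  per <- round(fs * epoch_seconds)
  off <- actiphen:::.minute_offset_samples(sig$start_time, fs)
  n <- length(sig$x)
  n_ep <- (n - off) %/% per
  counts <- integer(n_ep)
  for (axis in c("x", "y", "z")) {
    v <- sig[[axis]]
    for (i in 2:n) {
      if (v[i - 1] < tau && v[i] >= tau) {
        pos <- i - off
        if (pos >= 1 && pos <= n_ep * per)
          counts[(pos - 1) %/% per + 1] <- counts[(pos - 1) %/% per + 1] + 1L
      }
    }
  }
  counts
}

# exhaustive circular window search for M10/L5 on one day of epochs
brute_window_stats <- function(day, w) {
  n <- length(day)
  means <- vapply(seq_len(n), function(s) {
    idx <- ((s - 1) + 0:(w - 1)) %% n + 1
    mean(day[idx])
  }, numeric(1))
  c(max = max(means), min = min(means))
}

# exhaustive maximal-clique enumeration on an adjacency matrix
brute_max_cliques <- function(adj, min_size) {
  n <- nrow(adj)
  out <- list()
  for (k in min_size:n) {
    for (comb in utils::combn(n, k, simplify = FALSE)) {
      sub <- adj[comb, comb, drop = FALSE]
      diag(sub) <- TRUE
      if (all(sub)) {
        # maximal iff no outside vertex is adjacent to every member
        ext <- setdiff(seq_len(n), comb)
        if (!any(vapply(ext, function(v) all(adj[v, comb]), logical(1))))
          out[[length(out) + 1L]] <- comb
      }
    }
  }
  out
}

# direct double-sum Morlet CWT (Torrence & Compo normalization)
brute_morlet <- function(x, periods, omega0 = 6, dt = 1) {
  n <- length(x)
  scales <- periods * (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
  co <- matrix(0, length(scales), n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    for (t in seq_len(n)) {
      eta <- ((seq_len(n) - t) * dt) / s
      psi <- pi^(-1 / 4) * exp(1i * omega0 * eta) * exp(-eta^2 / 2)
      co[si, t] <- Re(sum(x * Conj(psi)) * sqrt(dt / s))
    }
  }
  co
}

# closed-form Shapley values of a linear model under marginal replacement
linear_shap <- function(coef, X, B) {
  sweep(X, 2, colMeans(B), "-") %*% diag(coef, length(coef)) |>
    (\(m) {dimnames(m) <- dimnames(X); m})()
}

fixed_linear_model <- function(coef, intercept = 0, features = names(coef)) {
  structure(list(algorithm = "fixed_linear",
                 fit = list(coef = coef, intercept = intercept),
                 features = features),
            class = "acti_model")
}

# quick low-cost profile for smoke tests (all stochastic sources mild)
quick_profile <- function(...) group_profile(...)
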