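# internal helpers shared across modules

# population standard deviation (divide by N); singleton -> 0
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n == 1L) return(0)
  sqrt(sum((x - mean(x))^2) / n)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# deterministic child seed derived from a parent seed and an index
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# maximal runs where `flag` is TRUE; returns data.frame(start, end) with
# inclusive start, exclusive end (1-based indices)
true_runs <- function(flag) {
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], end = ends[keep] + 1L)
}

# summary statistics used throughout the nocturnal feature families
family_stats <- function(x) {
  if (length(x) == 0L || all(is.na(x)))
    return(c(min = NA_real_, max = NA_real_, avg = NA_real_, median = NA_real_))
  c(min = min(x), max = max(x), avg = mean(x), median = stats::median(x))
}
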