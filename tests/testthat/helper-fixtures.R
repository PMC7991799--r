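# Shared fixtures, built in code. Expensive synthetic sequences are cached
# per test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small constant-intensity frame
flat_frame <- function(value = 1000L, nr = 32, nc = 40, bit_depth = 16L) {
  wound_frame(matrix(as.integer(value), nr, nc), bit_depth, pixel_size_um = 2)
}

# Quick low-resolution simulation config for unit tests (not the benchmark)
quick_config <- function(...) {
  sim_config(duration_hours = 2, ...)
}

# One mid-closure synthetic frame plus ground truth, reused across files
default_scene <- function() {
  cached("default_scene", {
    cfg <- sim_config(seed = 7)
    sq <- simulate_sequence(cfg, frames = c(1L, 20L))
    list(config = cfg, seq = sq,
         enhanced = enhance(sq$frames[[2]], benchmark_filter_params()))
  })
}

# Brute-force trailing moving average (oracle for build_series smoothing)
trailing_mean_oracle <- function(x, N) {
  vapply(seq_along(x), function(i) mean(x[max(1, i - N + 1):i]), numeric(1))
}

# Closed-form simple-regression oracle (slope, SEM, r2, 95% CI)
ols_oracle <- function(t, y) {
  n <- length(t)
  sxx <- sum((t - mean(t))^2)
  slope <- sum((t - mean(t)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(t)
  res <- y - intercept - slope * t
  rss <- sum(res^2); syy <- sum((y - mean(y))^2)
  sem <- sqrt(rss / (n - 2) / sxx)
  tc <- qt(0.975, n - 2)
  list(slope = slope, sem = sem, r2 = 1 - rss / syy,
       ci95 = c(slope - tc * sem, slope + tc * sem))
}

# Closed-form pooled two-sample t-test oracle
t_test_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), nx + ny - 2)
}

# Independent per-pixel local entropy (mirrors the documented definition:
# disk neighbourhood, reflect indexing, half-bin-offset quantisation)
entropy_oracle <- function(img, i, j, radius, bins) {
  reflect <- function(k, n) {
    if (n == 1) return(1L)
    period <- 2 * n - 2
    k <- (k - 1) %% period
    if (k < 0) k <- k + period
    if (k < n) k + 1L else period - k + 1L
  }
  lev <- c()
  for (a in -radius:radius) for (b in -radius:radius) {
    if (a * a + b * b <= radius * radius) {
      v <- img[reflect(i + a, nrow(img)), reflect(j + b, ncol(img))]
      v <- min(max(v, 0), 1)
      lev <- c(lev, min(floor(v * bins + 0.5), bins - 1))
    }
  }
  p <- as.numeric(table(lev)) / length(lev)
  -sum(p * log2(p))
}
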