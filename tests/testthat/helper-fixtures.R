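# fixture builders and independent brute-force oracles

# grid_ts from a function of (time, row, col) or a constant
make_gts <- function(f, n_years = 3, months = 4:10, h = 3, w = 3,
                     start_year = 2000, role = "NDVI", half = NULL) {
  nm <- length(months)
  reps <- if (is.null(half)) 1L else length(half)
  time <- data.frame(year = rep(start_year + seq_len(n_years) - 1L,
                                each = nm * reps),
                     month = rep(rep(months, each = reps), n_years))
  if (!is.null(half)) time$half <- rep(half, nm * n_years)
  nt <- nrow(time)
  vals <- array(NA_real_, c(nt, h, w))
  for (t in seq_len(nt)) for (i in seq_len(h)) for (j in seq_len(w))
    vals[t, i, j] <- if (is.function(f)) f(t, i, j) else f
  grid_ts(vals, time, lat = seq_len(h), lon = seq_len(w), role = role)
}

# O(n^2) oracles, written as explicit loops, independent of the implementation
brute_sen <- function(y, t = seq_along(y)) {
  sl <- c()
  n <- length(y)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (t[j] != t[i]) sl <- c(sl, (y[j] - y[i]) / (t[j] - t[i]))
  median(sl)
}

brute_mk <- function(y) {
  n <- length(y)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(y[j] - y[i])
  tie_term <- 0
  for (v in unique(y)) {
    tt <- sum(y == v)
    if (tt > 1) tie_term <- tie_term + tt * (tt - 1) * (2 * tt + 5)
  }
  var_s <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  z <- if (var_s <= 0) 0
  else if (s > 0) (s - 1) / sqrt(var_s)
  else if (s < 0) (s + 1) / sqrt(var_s)
  else 0
  list(s = s, var_s = var_s, z = z)
}

# varimax simplicity criterion (raw, no normalization): sum over modes of the
# variance of squared loadings
vm_crit <- function(loadings_mode_by_pixel) {
  a2 <- loadings_mode_by_pixel^2
  sum(apply(a2, 1L, function(v) mean(v^2) - mean(v)^2))
}

# all value sequences of length n over a finite alphabet, as a matrix
all_series <- function(n, vals = 0:2) {
  as.matrix(expand.grid(rep(list(vals), n)))
}
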