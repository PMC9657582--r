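make_anomaly_set <- function(ndvi, tem, pre, rad) {
  p <- ncol(ndvi)
  structure(list(ndvi = ndvi, tem = tem, pre = pre, rad = rad,
                 pixel_index = cbind(row = seq_len(p), col = rep(1L, p)),
                 months = rep(4:10, length.out = nrow(ndvi)),
                 dim = c(p, 1L)),
            class = "anomaly_set")
}

test_that("anomalies are deseasonalized and detrended to numerical zero", {
  f <- function(t, i, j) 0.4 + 0.1 * sin((t - 1) %% 7) + 0.001 * t
  g <- make_gts(f, n_years = 10, months = 4:10, h = 3, w = 3)
  gt <- make_gts(f, n_years = 10, months = 4:10, h = 3, w = 3, role = "TEM")
  gp <- make_gts(f, n_years = 10, months = 4:10, h = 3, w = 3, role = "PRE")
  gr <- make_gts(f, n_years = 10, months = 4:10, h = 3, w = 3, role = "RAD")
  an <- make_anomalies(g, gt, gp, gr)
  # seasonal + linear input leaves only the within-year sampling residue of
  # the trend (order trend x season length)
  expect_lt(max(abs(an$ndvi)), 0.01)
  expect_lt(abs(mean(an$ndvi[, 1])), 1e-8)
  # per-calendar-month means stay near zero after detrending
  for (mo in 4:10)
    expect_lt(abs(mean(an$ndvi[an$months == mo, 1])), 5e-3)
  # zero linear trend
  expect_lt(abs(ols_trend(an$ndvi[, 1])), 1e-10)
})

test_that("climate weights isolate a single planted driver", {
  set.seed(21)
  n <- 238
  z <- matrix(rnorm(3 * n), n, 3)
  ndvi <- 0.5 * z[, 2] + rnorm(n, sd = 1e-4)
  w <- climate_weights(ndvi, z[, 1], z[, 2], z[, 3])
  expect_equal(unname(w["PRE"]), 1, tolerance = 0.01)
  expect_equal(sum(w), 1, tolerance = 1e-9)
})

test_that("a zero-variance predictor gets weight zero with renormalization", {
  set.seed(22)
  n <- 120
  z <- matrix(rnorm(2 * n), n, 2)
  ndvi <- 0.3 * z[, 1] + 0.3 * z[, 2] + rnorm(n, sd = 0.05)
  expect_warning(w <- climate_weights(ndvi, z[, 1], z[, 2], rep(1, n)),
                 "zero-variance")
  expect_equal(unname(w["RAD"]), 0)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_error(climate_weights(1:10, 1:10, 1:10, 1:10), "60")
})

test_that("weights approach (1/3, 1/3, 1/3) under equal planted couplings", {
  set.seed(23)
  reps <- 50
  n <- 238
  ws <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    z <- matrix(rnorm(3 * n), n, 3)
    ndvi <- 0.02 * rowSums(z) + rnorm(n, sd = 0.02)
    ws[r, ] <- climate_weights(ndvi, z[, 1], z[, 2], z[, 3])
  }
  expect_equal(colMeans(ws), rep(1 / 3, 3), tolerance = 0.02)
})

test_that("mean precipitation weight is monotone in the planted coupling", {
  set.seed(24)
  n <- 238
  mean_w <- sapply(c(0.2, 0.5, 1.0), function(beta_pre) {
    mean(replicate(50, {
      z <- matrix(rnorm(3 * n), n, 3)
      ndvi <- 0.2 * z[, 1] + beta_pre * z[, 2] + 0.2 * z[, 3] +
        rnorm(n, sd = 0.2)
      climate_weights(ndvi, z[, 1], z[, 2], z[, 3])["PRE"]
    }))
  })
  expect_true(all(diff(mean_w) > 0))
})

test_that("variance-percentile sensitivities follow the rank construction", {
  set.seed(25)
  n <- 70
  p <- 20
  # climate variances identical across pixels; NDVI variances strictly ordered
  clim <- matrix(rep(rnorm(n), p), n, p)
  ndvi <- sapply(seq_len(p), function(k) scale(rnorm(n))[, 1] * k)
  an <- make_anomaly_set(ndvi, clim, clim, clim)
  s <- climate_sensitivities(an)
  # equal climate variance -> all climate percentiles tie at the mid-rank
  # mean; NDVI percentile of pixel k is k/p*100
  clim_pct <- mean(seq_len(p)) / p * 100
  expect_equal(s[, "TEM"], (seq_len(p) / p * 100) / clim_pct,
               tolerance = 1e-10)
  # pixels at the 25th vs 75th percentile have sensitivity ratio 1:3
  expect_equal(unname(s[15, "PRE"] / s[5, "PRE"]), 3, tolerance = 1e-10)
  # median pixel at median climate variance scores about 1 (here: exactly
  # the mid-rank ratio)
  expect_error(climate_sensitivities(make_anomaly_set(
    ndvi[, 1:3], clim[, 1:3], clim[, 1:3], clim[, 1:3])), "10")
})

test_that("the weighted-sum score and contributions follow the index formula", {
  w <- rbind(c(0.2, 0.5, 0.3), c(1, 0, 0), c(1 / 3, 1 / 3, 1 / 3))
  s <- rbind(c(1, 2, 1), c(0.7, 9, 9), c(2, 2, 2))
  r <- compute_vsi(w, s)
  expect_equal(r$raw, c(1.5, 0.7, 2), tolerance = 1e-12)
  expect_equal(r$contribution[1, ],
               c(TEM = 100 * 0.2 / 1.5, PRE = 100 * 1 / 1.5,
                 RAD = 100 * 0.3 / 1.5), tolerance = 1e-12)
  expect_equal(unname(r$contribution[2, ]), c(100, 0, 0))
  expect_equal(unname(r$contribution[3, ]), rep(100 / 3, 3), tolerance = 1e-12)
  expect_equal(r$dominant, c(2L, 1L, 1L))   # ties go to TEM
  expect_true(all(abs(rowSums(r$contribution) - 100) < 1e-6))
  # degenerate zero score is flagged with uniform contributions
  r0 <- compute_vsi(rbind(c(0.5, 0.5, 0), c(0.2, 0.3, 0.5)),
                    rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_true(r0$degenerate[1])
  expect_equal(unname(r0$contribution[1, ]), rep(100 / 3, 3))
})

test_that("the final index is uniform on (0, 100] by construction", {
  set.seed(26)
  n <- 10000
  w <- matrix(runif(3 * n), n, 3)
  w <- w / rowSums(w)
  s <- matrix(rexp(3 * n), n, 3)
  r <- compute_vsi(w, s)
  expect_true(all(r$vsi > 0 & r$vsi <= 100))
  # Kolmogorov-Smirnov distance against uniform
  u <- sort(r$vsi) / 100
  ks <- max(pmax(abs(u - seq_len(n) / n), abs(u - (seq_len(n) - 1) / n)))
  expect_lt(ks, 0.01)
})

test_that("regional summaries recover the planted dominant driver", {
  cf <- synth_config(grid_height = 12, grid_width = 12, n_years = 20,
                     n_regions = 1, beta = matrix(c(0.002, 0.05, 0.002), 1, 3),
                     noise_sd = 0.02, region_mode_sd = 0, ar1_rho = 0.2,
                     rng_seed = 31)
  ds <- generate_dataset(cf)
  vs <- vsi_pipeline(ds$ndvi, ds$tem, ds$pre, ds$rad)
  rg <- spatial_refine(matrix(1L, 12, 12))
  rs <- region_summary(vs, rg, ds$tem, ds$pre, ds$rad)
  expect_equal(nrow(rs), 1L)
  expect_equal(rs$dominant, "PRE")
  expect_gt(rs$contribution_PRE, rs$contribution_TEM)
  expect_gt(rs$contribution_PRE, rs$contribution_RAD)
  expect_equal(rs$contribution_TEM + rs$contribution_PRE +
                 rs$contribution_RAD, 100, tolerance = 1e-9)
  expect_equal(rs$vsi, mean(vs$vsi), tolerance = 1e-9)
})
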