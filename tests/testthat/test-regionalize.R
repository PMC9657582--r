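test_that("anomaly construction removes the monthly climatology", {
  # pure seasonal cycle -> all-zero anomalies
  g <- make_gts(function(t, i, j) sin((t - 1) %% 7), n_years = 4,
                months = 4:10, h = 2, w = 2)
  am <- build_anomaly_matrix(g)
  expect_lt(max(abs(am$anomalies)), 1e-12)

  # values (1,2,3) for one calendar month across 3 years -> (-1, 0, 1)
  g2 <- make_gts(function(t, i, j) ((t - 1) %/% 2) + 1, n_years = 3,
                 months = 4:5, h = 2, w = 2)
  am2 <- build_anomaly_matrix(g2)
  a_month4 <- am2$anomalies[am2$months == 4, 1]
  expect_equal(a_month4, c(-1, 0, 1))
})

test_that("pixels with missing months are excluded from the anomaly matrix", {
  g <- make_gts(function(t, i, j) rnorm(1), n_years = 3, months = 4:10,
                h = 3, w = 3)
  g$values[5, 2, 2] <- NA
  expect_message(am <- build_anomaly_matrix(g), "excluded")
  expect_equal(ncol(am$anomalies), 8L)
})

test_that("EOF decomposition conserves variance and recovers planted modes", {
  # rank-1: one spatial pattern x one time series -> EOF1 explains 100%
  u <- sin(seq(0, 3, length.out = 20))
  v <- rnorm(15)
  e1 <- eof_decompose(outer(u, v))
  expect_equal(e1$explained_fraction[1], 1, tolerance = 1e-12)

  # two orthogonal planted modes with 4:1 variance -> fractions 0.8 / 0.2
  qtime <- qr.Q(qr(matrix(rnorm(40 * 2), 40, 2)))
  qpix <- qr.Q(qr(matrix(rnorm(30 * 2), 30, 2)))
  x <- 2 * outer(qtime[, 1], qpix[, 1]) + 1 * outer(qtime[, 2], qpix[, 2])
  e2 <- eof_decompose(x)
  expect_equal(e2$explained_fraction[1:2], c(0.8, 0.2), tolerance = 1e-6)

  # white noise: fractions sum to 1, eigenvalues descending >= 0
  set.seed(2)
  e3 <- eof_decompose(matrix(rnorm(20 * 50), 20, 50))
  expect_equal(sum(e3$explained_fraction), 1, tolerance = 1e-10)
  expect_true(all(diff(e3$eigenvalues) <= 1e-12))
  expect_true(all(e3$eigenvalues >= 0))
})

test_that("EOF reconstruction from all modes reproduces the input", {
  set.seed(4)
  x <- matrix(rnorm(25 * 40), 25, 40)
  e <- eof_decompose(x)
  expect_lt(max(abs(eof_reconstruct(e) - x)) / max(abs(x)), 1e-8)
})

test_that("North's Rule margins match the closed form", {
  # lambda = (10, 1, 0.1), N = 100: margin_1 = 9 - 10 sqrt(0.02)
  m <- north_margin(c(10, 1, 0.1), 100)
  expect_equal(m[1], 9 - 10 * sqrt(2 / 100), tolerance = 1e-12)
  expect_equal(m[1], 7.585786, tolerance = 1e-6)
  # equal eigenvalues are never separated
  expect_true(all(north_margin(c(5, 5), 50)[1] < 0))
})

test_that("mode retention honours the cumulative-variance target", {
  lam <- c(10, 1, 0.1, 0.05, 0.01)
  e <- structure(list(eigenvalues = lam,
                      explained_fraction = lam / sum(lam),
                      cumulative_fraction = cumsum(lam / sum(lam)),
                      n_samples = 100), class = "eof_result")
  r <- retain_by_north(e, 0.85)
  expect_equal(r$n_retained, 1L)
  r2 <- retain_by_north(e, 0.99)
  expect_equal(r2$n_retained, 3L)
  expect_equal(nrow(r2$variance_table), 3L)
  expect_equal(r2$variance_table$north_margin,
               north_margin(lam, 100)[1:3], tolerance = 1e-12)
  # equal eigenvalues trigger a separation warning but are still retained
  lam3 <- c(5, 5, 0.1)
  e3 <- structure(list(eigenvalues = lam3,
                       explained_fraction = lam3 / sum(lam3),
                       cumulative_fraction = cumsum(lam3 / sum(lam3)),
                       n_samples = 50), class = "eof_result")
  expect_warning(r3 <- retain_by_north(e3, 0.9), "North")
  expect_equal(r3$n_retained, 2L)
})

test_that("varimax rotation is orthonormal, preserves communality, and cannot
           worsen an already simple structure", {
  # simple structure: each pixel loads on exactly one mode
  l0 <- rbind(c(2, 2, 2, 0, 0, 0, 0, 0),
              c(0, 0, 0, 1.5, 1.5, 0, 0, 0),
              c(0, 0, 0, 0, 0, 1, 1, 1))
  r <- varimax_rotate(l0, normalize = FALSE)
  expect_equal(t(r$rotation) %*% r$rotation, diag(3), tolerance = 1e-10)
  expect_equal(colSums(r$rlv^2), colSums(l0^2), tolerance = 1e-8)
  expect_gte(vm_crit(r$rlv), vm_crit(l0) - 1e-8)
})

test_that("varimax recovers a known 30-degree rotation of a simple structure", {
  l0 <- rbind(c(3, 3, 3, 3, 0, 0, 0, 0, 0, 0),
              c(0, 0, 0, 0, 2, 2, 2, 2, 2, 2))
  th <- pi / 6
  rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  mixed <- t(rot) %*% l0              # deliberately rotated away from simplicity
  r <- varimax_rotate(mixed, normalize = FALSE)
  expect_equal(vm_crit(r$rlv), vm_crit(l0), tolerance = 1e-8)
  # recovered RLVs match the original up to sign and mode permutation
  match_abs <- abs(cor(t(r$rlv), t(l0)))
  expect_equal(sort(apply(match_abs, 1, max)), c(1, 1), tolerance = 1e-6)
})

test_that("single-mode rotation falls back to the identity", {
  expect_message(r <- varimax_rotate(matrix(1:4, 1, 4)), "identity")
  expect_equal(r$rotation, diag(1))
  expect_equal(r$seed_pixels, 4L)
})

test_that("seeded K-means recovers well-separated clouds deterministically", {
  set.seed(7)
  feats <- rbind(matrix(rnorm(40, 0), 20, 2),
                 matrix(rnorm(40, 10), 20, 2),
                 matrix(rnorm(40, -10), 20, 2))
  seeds <- c(1L, 21L, 41L)
  lab <- kmeans_seeded(feats, seeds)
  expect_equal(lab, rep(1:3, each = 20))
  # convergence: labels equal brute-force nearest final centroid
  cents <- do.call(rbind, lapply(1:3, function(k)
    colMeans(feats[lab == k, , drop = FALSE])))
  nearest <- apply(feats, 1, function(x)
    which.min(colSums((t(cents) - x)^2)))
  expect_equal(lab, as.integer(nearest))
  # identical pixels are always co-assigned
  feats2 <- rbind(feats, feats[1, ], feats[1, ])
  lab2 <- kmeans_seeded(feats2, seeds)
  expect_equal(lab2[61], lab2[62])
  # k = 1 puts everything in one cluster
  expect_true(all(kmeans_seeded(feats, 1L) == 1L))
  # duplicate seeds are an error
  expect_error(kmeans_seeded(feats2, c(1L, 61L)), "duplicate")
})

test_that("spatial refinement is the identity on contiguous labels", {
  lab <- cbind(matrix(1L, 6, 3), matrix(2L, 6, 3))
  rm_ <- spatial_refine(lab, min_region_pixels = 1)
  expect_equal(sort(unique(as.vector(rm_$labels))), 1:2)
  expect_equal(table(rm_$labels)[["1"]], 18L)
})

test_that("small islands are absorbed into the neighbour with the longest boundary", {
  lab <- matrix(2L, 8, 8)
  lab[4, 4:5] <- 1L                    # 2-pixel island of cluster 1 inside 2
  rm_ <- spatial_refine(lab, min_region_pixels = 10)
  expect_equal(unique(as.vector(rm_$labels)), 1L)
  expect_equal(rm_$region_table$n_pixels, 64L)
})

test_that("disjoint blocks of one cluster are split into separate regions", {
  lab <- matrix(2L, 9, 9)
  lab[1:2, 1:2] <- 1L
  lab[8:9, 8:9] <- 1L                  # same cluster, two far-apart blocks
  rm_ <- spatial_refine(lab, min_region_pixels = 1)
  expect_equal(nrow(rm_$region_table), 3L)
  # the two blocks got different ids
  expect_false(rm_$labels[1, 1] == rm_$labels[9, 9])
  # labels are contiguous 1..R
  expect_setequal(unique(as.vector(rm_$labels)), 1:3)
  # with splitting disabled they stay one (multi-part) region
  rm2 <- spatial_refine(lab, min_region_pixels = 1, split = FALSE)
  expect_equal(nrow(rm2$region_table), 2L)
})

test_that("masked pixels stay unlabeled through refinement", {
  lab <- matrix(1L, 5, 5)
  lab[1, ] <- NA
  rm_ <- spatial_refine(lab, min_region_pixels = 1)
  expect_true(all(is.na(rm_$labels[1, ])))
  expect_equal(rm_$region_table$n_pixels, 20L)
})

test_that("the full pipeline recovers planted block regions", {
  cf <- synth_config(grid_height = 20, grid_width = 20, n_years = 15,
                     n_regions = 4, rng_seed = 7)
  ds <- generate_dataset(cf)
  rg <- suppressWarnings(regionalize_pipeline(ds$ndvi))
  ari <- mclust::adjustedRandIndex(rg$labels, ds$truth$region_labels)
  expect_gte(ari, 0.9)
  expect_equal(rg$variance_table$mode, seq_len(rg$n_retained))
  expect_gte(rg$variance_table$cumulative_pct[rg$n_retained], 85)
})

test_that("a single-region dataset yields a single region", {
  cf <- synth_config(grid_height = 8, grid_width = 8, n_years = 10,
                     n_regions = 1, beta = matrix(0, 1, 3),
                     noise_sd = 0, region_mode_sd = 0.05, ar1_rho = 0,
                     rng_seed = 3)
  ds <- generate_dataset(cf)
  rg <- suppressMessages(regionalize_pipeline(ds$ndvi))
  expect_equal(nrow(rg$region_table), 1L)
  expect_true(all(rg$labels == 1L))
})
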