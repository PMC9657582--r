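#' Deseasonalized, detrended anomaly series for sensitivity analysis
#'
#' Builds per-pixel monthly anomalies for NDVI and the three climate
#' variables: the per-calendar-month climatology is removed, then a linear
#' trend is subtracted, so each series has (numerically) zero mean and
#' zero linear trend. Only pixels valid and complete in all four grids
#' are retained.
#'
#' @param ndvi,tem,pre,rad aligned growing-season monthly [grid_ts()]
#'   objects on a common grid and time axis.
#' @return object of class `anomaly_set`: matrices `ndvi`, `tem`, `pre`,
#'   `rad` (`time x pixel`), `pixel_index`, `months`, `dim` (grid shape).
#' @export
make_anomalies <- function(ndvi, tem, pre, rad) {
  gl <- list(ndvi = ndvi, tem = tem, pre = pre, rad = rad)
  for (g in gl) stopifnot(inherits(g, "grid_ts"))
  d <- dim(ndvi$values)
  for (g in gl[-1L]) if (!identical(dim(g$values), d))
    stop("grids are not aligned", call. = FALSE)
  mask <- Reduce(`&`, lapply(gl, function(g) g$valid_mask))
  complete <- Reduce(`&`, lapply(gl, function(g)
    apply(g$values, c(2L, 3L), function(v) all(is.finite(v)))))
  ok <- mask & complete
  idx <- which(ok, arr.ind = TRUE)
  months <- ndvi$time$month
  out <- lapply(gl, function(g) {
    m <- matrix(NA_real_, d[1L], nrow(idx))
    for (p in seq_len(nrow(idx))) m[, p] <- g$values[, idx[p, 1L], idx[p, 2L]]
    detrend_linear(deseasonalize(m, months))
  })
  structure(list(ndvi = out$ndvi, tem = out$tem, pre = out$pre,
                 rad = out$rad, pixel_index = idx, months = months,
                 dim = d[2:3]),
            class = "anomaly_set")
}

#' Climate weights for one pixel
#'
#' Relative importance of temperature, precipitation and radiation
#' variability for NDVI variability, estimated Seddon-style: the three
#' climate anomaly series are standardized and regressed against the NDVI
#' anomaly via principal-component regression (components retaining at
#' least `pc_var` of the predictor variance) with a lag-1 NDVI
#' autoregressive control term. Weights are the absolute back-transformed
#' coefficients of the climate variables, normalized to sum to 1; the AR
#' term is excluded from the normalization. A zero-variance predictor
#' receives weight 0 (with a warning) and the remainder is renormalized.
#'
#' @param ndvi_a,tem_a,pre_a,rad_a anomaly series for one pixel (equal
#'   length, >= 60 months).
#' @param pc_var predictor variance fraction the retained components must
#'   reach (default 0.95).
#' @return named numeric vector `c(TEM =, PRE =, RAD =)` summing to 1.
#' @export
climate_weights <- function(ndvi_a, tem_a, pre_a, rad_a, pc_var = 0.95) {
  n <- length(ndvi_a)
  if (n < 60L) stop("need >= 60 monthly samples", call. = FALSE)
  x <- cbind(TEM = tem_a, PRE = pre_a, RAD = rad_a)
  sds <- apply(x, 2L, stats::sd)
  live <- sds > 0
  if (!all(live))
    warning("zero-variance climate predictor(s): ",
            paste(colnames(x)[!live], collapse = ", "),
            "; weight set to 0", call. = FALSE)
  w <- c(TEM = 0, PRE = 0, RAD = 0)
  if (!any(live)) return(w)
  z <- scale(x[, live, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  varfrac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(varfrac >= pc_var - 1e-12)[1L]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  y <- ndvi_a[-1L]
  lag1 <- ndvi_a[-n]
  fit <- stats::lm.fit(cbind(1, scores[-1L, , drop = FALSE], lag1), y)
  beta_pc <- fit$coefficients[1L + seq_len(k)]
  beta_pc[is.na(beta_pc)] <- 0
  beta <- pc$rotation[, seq_len(k), drop = FALSE] %*% beta_pc
  w[live] <- abs(as.numeric(beta))
  if (sum(w) > 0) w <- w / sum(w)
  w
}

#' Climate weights for every pixel of an anomaly set
#'
#' @param anoms an [make_anomalies()] result.
#' @param pc_var passed to [climate_weights()].
#' @return `(pixel x 3)` matrix with columns TEM, PRE, RAD, rows summing
#'   to 1.
#' @export
climate_weights_grid <- function(anoms, pc_var = 0.95) {
  stopifnot(inherits(anoms, "anomaly_set"))
  p <- ncol(anoms$ndvi)
  w <- matrix(NA_real_, p, 3L, dimnames = list(NULL, c("TEM", "PRE", "RAD")))
  for (i in seq_len(p))
    w[i, ] <- climate_weights(anoms$ndvi[, i], anoms$tem[, i],
                              anoms$pre[, i], anoms$rad[, i], pc_var)
  w
}

#' Variance-percentile climate sensitivities
#'
#' For each climate variable k, a pixel's sensitivity is the ratio of two
#' domain-wide percentile scores: the percentile of its NDVI-anomaly
#' variance divided by the percentile of its climate-k-anomaly variance.
#' Percentiles are mid-rank scores `rank / N * 100` in `(0, 100]`
#' (average ranks for ties), so sensitivities are deterministic and
#' tie-stable; a pixel at the domain median of both variances scores 1.
#'
#' @param anoms an [make_anomalies()] result with >= 10 valid pixels.
#' @return `(pixel x 3)` matrix of sensitivities, columns TEM, PRE, RAD.
#' @export
climate_sensitivities <- function(anoms) {
  stopifnot(inherits(anoms, "anomaly_set"))
  p <- ncol(anoms$ndvi)
  if (p < 10L) stop("percentile scores need >= 10 valid pixels", call. = FALSE)
  pct <- function(v) rank(v, ties.method = "average") / length(v) * 100
  nv <- pct(apply(anoms$ndvi, 2L, stats::var))
  out <- sapply(c("tem", "pre", "rad"), function(nm)
    nv / pct(apply(anoms[[nm]], 2L, stats::var)))
  colnames(out) <- c("TEM", "PRE", "RAD")
  out
}

#' Vegetation Sensitivity Index from weights and sensitivities
#'
#' Per pixel, the raw score is the weighted sum
#' `VSI_raw = TEMwei * TEMsen + PREwei * PREsen + RADwei * RADsen`;
#' the reported VSI is the mid-rank percentile of the raw score across the
#' valid domain, scaled to `(0, 100]`. Per-variable contributions are
#' `100 * w_k * sens_k / VSI_raw` and sum to 100; the dominant driver is
#' the variable with the largest contribution (ties to the lowest index,
#' TEM < PRE < RAD). A raw score of exactly 0 gets uniform contributions
#' (flagged in `degenerate`).
#'
#' @param weights `(pixel x 3)` weight matrix (rows sum to 1).
#' @param sens `(pixel x 3)` sensitivity matrix.
#' @return object of class `vsi_result`: vectors `vsi`, `raw`,
#'   `dominant` (integer 1 = TEM, 2 = PRE, 3 = RAD), `degenerate`
#'   (logical), and matrices `weights`, `sens`, `contribution`
#'   (percent).
#' @export
compute_vsi <- function(weights, sens) {
  weights <- as.matrix(weights); sens <- as.matrix(sens)
  stopifnot(identical(dim(weights), dim(sens)), ncol(weights) == 3L)
  raw <- rowSums(weights * sens)
  vsi <- rank(raw, ties.method = "average") / length(raw) * 100
  contrib <- 100 * (weights * sens) / raw
  degenerate <- raw == 0
  if (any(degenerate)) contrib[degenerate, ] <- 100 / 3
  dominant <- max.col(contrib, ties.method = "first")
  colnames(contrib) <- c("TEM", "PRE", "RAD")
  structure(list(vsi = vsi, raw = raw, weights = weights, sens = sens,
                 contribution = contrib, dominant = as.integer(dominant),
                 degenerate = degenerate),
            class = "vsi_result")
}

#' Full VSI chain on aligned grids
#'
#' Composes [make_anomalies()], [climate_weights_grid()],
#' [climate_sensitivities()] and [compute_vsi()], mapping results back to
#' the grid.
#'
#' @inheritParams make_anomalies
#' @param pc_var passed to [climate_weights()].
#' @return a `vsi_result` with extra fields `pixel_index`, `dim`, and
#'   `grids`: a list of `(y, x)` matrices (`vsi`, `dominant`,
#'   `contribution_TEM/PRE/RAD`).
#' @export
vsi_pipeline <- function(ndvi, tem, pre, rad, pc_var = 0.95) {
  anoms <- make_anomalies(ndvi, tem, pre, rad)
  w <- climate_weights_grid(anoms, pc_var)
  s <- climate_sensitivities(anoms)
  res <- compute_vsi(w, s)
  res$pixel_index <- anoms$pixel_index
  res$dim <- anoms$dim
  to_grid <- function(v) {
    m <- matrix(NA_real_, anoms$dim[1L], anoms$dim[2L])
    m[anoms$pixel_index] <- v
    m
  }
  res$grids <- list(vsi = to_grid(res$vsi),
                    dominant = to_grid(res$dominant),
                    contribution_TEM = to_grid(res$contribution[, 1L]),
                    contribution_PRE = to_grid(res$contribution[, 2L]),
                    contribution_RAD = to_grid(res$contribution[, 3L]))
  res
}

#' Regional summary of VSI and climate trends
#'
#' Per region: mean VSI, mean per-variable contributions renormalized to
#' sum to 100, the dominant variable of the mean contributions, and
#' Theil-Sen trends of the regional-mean annual growing-season climate
#' series with Mann-Kendall significance stars at 95%.
#'
#' @param vsires a [vsi_pipeline()] result (with `grids`).
#' @param regions a `region_map` (labels aligned with the VSI grid).
#' @param tem,pre,rad the growing-season monthly climate [grid_ts()]
#'   objects used for the trends.
#' @return `data.table` with one row per region: mean VSI, contribution
#'   percentages, dominant driver, climate trends and significance flags.
#' @export
region_summary <- function(vsires, regions, tem, pre, rad) {
  stopifnot(inherits(vsires, "vsi_result"), inherits(regions, "region_map"))
  lab <- regions$labels
  if (!identical(dim(lab), dim(vsires$grids$vsi)))
    stop("region map is not aligned with the VSI grid", call. = FALSE)
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[!is.na(ids)]
  clim <- list(TEM = tem, PRE = pre, RAD = rad)
  rows <- lapply(ids, function(r) {
    inreg <- !is.na(lab) & lab == r
    vs <- vsires$grids$vsi[inreg]
    if (!any(is.finite(vs)))
      return(data.table::data.table(region = r, n_pixels = sum(inreg),
                                    vsi = NA_real_))
    co <- c(mean(vsires$grids$contribution_TEM[inreg], na.rm = TRUE),
            mean(vsires$grids$contribution_PRE[inreg], na.rm = TRUE),
            mean(vsires$grids$contribution_RAD[inreg], na.rm = TRUE))
    co <- 100 * co / sum(co)
    row <- data.table::data.table(
      region = r, n_pixels = sum(inreg),
      vsi = mean(vs, na.rm = TRUE),
      contribution_TEM = co[1L], contribution_PRE = co[2L],
      contribution_RAD = co[3L],
      dominant = c("TEM", "PRE", "RAD")[which.max(co)])
    for (nm in names(clim)) {
      g <- clim[[nm]]
      am <- annual_means(g)
      # regional-mean annual series
      series <- apply(am$values, 1L, function(sl) mean(sl[inreg], na.rm = TRUE))
      mk <- mk_test(series)
      row[[paste0("trend_", nm)]] <- sen_slope(series, am$years)
      row[[paste0("sig_", nm)]] <- is.finite(mk$p) && mk$p < 0.05
    }
    row
  })
  data.table::rbindlist(rows, fill = TRUE)
}
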