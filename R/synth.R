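#' Configuration for the synthetic gridded dataset generator
#'
#' Builds a validated configuration describing a multi-year, growing-season
#' monthly NDVI cube plus three climate cubes (temperature, precipitation,
#' shortwave radiation) with planted regional structure: each region has its
#' own NDVI baseline, seasonal amplitude, linear trend, climate couplings
#' and an independent regional anomaly mode, so every downstream stage
#' (trends, regionalization, sensitivity) has recoverable ground truth.
#'
#' Defaults emulate the study conditions the package targets: a 40 x 40
#' grid, 34 years of 7 growing-season months (April-October), four regions,
#' NDVI trends of order 1e-3 per year, and regional anomaly modes roughly
#' an order of magnitude stronger (in variance) than pixel noise.
#'
#' Per-region parameters (`ndvi_base`, `seasonal_amplitude`, `trend`,
#' `ar1_rho`, `noise_sd`, `region_mode_sd`) are scalars recycled across
#' regions or length-`n_regions` vectors. `beta` is an `n_regions x 3`
#' matrix of couplings (NDVI index units per standardized climate anomaly),
#' columns ordered TEM, PRE, RAD.
#'
#' @param grid_height,grid_width grid dimensions (>= 2).
#' @param n_years number of years.
#' @param months_per_year growing-season months per year (default 7).
#' @param start_month first growing-season calendar month (default 4, April).
#' @param start_year first calendar year.
#' @param n_regions number of planted regions (>= 1).
#' @param partition_mode `"blocks"` (rectangular tiling) or `"voronoi"`
#'   (nearest random seed point).
#' @param ndvi_base NDVI baseline per region (index units).
#' @param seasonal_amplitude NDVI seasonal amplitude per region.
#' @param trend NDVI linear trend per region (index units / yr).
#' @param beta `n_regions x 3` coupling matrix (TEM, PRE, RAD columns).
#' @param ar1_rho AR(1) memory of the NDVI anomaly, `|rho| < 1`.
#' @param noise_sd NDVI innovation noise sd (index units, >= 0).
#' @param region_mode_sd sd of the region-specific shared temporal anomaly
#'   mode (index units); gives each region a distinct temporal signature.
#' @param climate list with one entry per variable (`TEM`, `PRE`, `RAD`),
#'   each a list `mean`, `seasonal_amplitude`, `trend`, `anomaly_sd`,
#'   `corr_length` (spatial e-folding length in pixels; 0 = independent).
#' @param rng_seed integer seed; the same seed and config give bit-identical
#'   output.
#'
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(grid_height = 40L, grid_width = 40L,
                         n_years = 34L, months_per_year = 7L,
                         start_month = 4L, start_year = 1982L,
                         n_regions = 4L,
                         partition_mode = c("blocks", "voronoi"),
                         ndvi_base = 0.5, seasonal_amplitude = 0.15,
                         trend = 0.0015,
                         beta = NULL,
                         ar1_rho = 0.2, noise_sd = 0.015,
                         region_mode_sd = 0.05,
                         climate = NULL,
                         rng_seed = 1L) {
  partition_mode <- match.arg(partition_mode)
  chk <- function(cond, field, msg)
    if (!cond) stop("invalid config: `", field, "` ", msg, call. = FALSE)
  chk(grid_height >= 2, "grid_height", "must be >= 2")
  chk(grid_width >= 2, "grid_width", "must be >= 2")
  chk(n_years >= 1, "n_years", "must be >= 1")
  chk(months_per_year >= 1 && months_per_year <= 12, "months_per_year",
      "must be in 1..12")
  chk(start_month >= 1 && start_month + months_per_year - 1 <= 12,
      "start_month", "must keep the season inside the calendar year")
  chk(n_regions >= 1, "n_regions", "must be >= 1")
  n_regions <- as.integer(n_regions)
  rec <- function(x, field) {
    chk(length(x) %in% c(1L, n_regions), field,
        "must be scalar or length n_regions")
    rep_len(as.numeric(x), n_regions)
  }
  ndvi_base <- rec(ndvi_base, "ndvi_base")
  seasonal_amplitude <- rec(seasonal_amplitude, "seasonal_amplitude")
  trend <- rec(trend, "trend")
  ar1_rho <- rec(ar1_rho, "ar1_rho")
  noise_sd <- rec(noise_sd, "noise_sd")
  region_mode_sd <- rec(region_mode_sd, "region_mode_sd")
  chk(all(abs(ar1_rho) < 1), "ar1_rho", "must satisfy |rho| < 1")
  chk(all(noise_sd >= 0), "noise_sd", "must be >= 0")
  chk(all(region_mode_sd >= 0), "region_mode_sd", "must be >= 0")
  if (is.null(beta)) {
    beta <- matrix(rep(c(0.010, 0.020, 0.015), each = n_regions), n_regions, 3L)
  } else {
    beta <- as.matrix(beta)
    if (nrow(beta) == 1L && n_regions > 1L)
      beta <- beta[rep(1L, n_regions), , drop = FALSE]
    chk(nrow(beta) == n_regions && ncol(beta) == 3L, "beta",
        "must be an n_regions x 3 matrix (TEM, PRE, RAD)")
  }
  dimnames(beta) <- list(paste0("region_", seq_len(n_regions)),
                         c("TEM", "PRE", "RAD"))
  default_climate <- list(
    TEM = list(mean = 15,  seasonal_amplitude = 8,  trend = 0.04,
               anomaly_sd = 1.0, corr_length = 10),
    PRE = list(mean = 80,  seasonal_amplitude = 40, trend = -0.40,
               anomaly_sd = 15,  corr_length = 10),
    RAD = list(mean = 220, seasonal_amplitude = 60, trend = -0.10,
               anomaly_sd = 10,  corr_length = 10))
  if (is.null(climate)) climate <- default_climate
  for (v in c("TEM", "PRE", "RAD")) {
    chk(v %in% names(climate), paste0("climate$", v), "is missing")
    climate[[v]] <- utils::modifyList(default_climate[[v]], climate[[v]])
    chk(climate[[v]]$anomaly_sd > 0, paste0("climate$", v, "$anomaly_sd"),
        "must be > 0")
    chk(climate[[v]]$corr_length >= 0, paste0("climate$", v, "$corr_length"),
        "must be >= 0")
  }
  structure(list(grid_height = as.integer(grid_height),
                 grid_width = as.integer(grid_width),
                 n_years = as.integer(n_years),
                 months_per_year = as.integer(months_per_year),
                 start_month = as.integer(start_month),
                 start_year = as.integer(start_year),
                 n_regions = as.integer(n_regions),
                 partition_mode = partition_mode,
                 ndvi_base = ndvi_base,
                 seasonal_amplitude = seasonal_amplitude,
                 trend = trend, beta = beta, ar1_rho = ar1_rho,
                 noise_sd = noise_sd, region_mode_sd = region_mode_sd,
                 climate = climate, rng_seed = as.integer(rng_seed)),
            class = "synth_config")
}

# run code with a private RNG stream, restoring global state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# rectangular tiling into n nearly equal blocks
partition_blocks <- function(h, w, n) {
  nr <- floor(sqrt(n))
  while (n %% nr != 0L) nr <- nr - 1L
  nc <- n %/% nr
  row_band <- pmin(((seq_len(h) - 1L) * nr) %/% h + 1L, nr)
  col_band <- pmin(((seq_len(w) - 1L) * nc) %/% w + 1L, nc)
  outer(row_band, col_band, function(r, c) (r - 1L) * nc + c)
}

# nearest-seed (Voronoi) partition; ties go to the lowest region index
partition_voronoi <- function(h, w, n) {
  sy <- stats::runif(n, 0.5, h + 0.5)
  sx <- stats::runif(n, 0.5, w + 0.5)
  lab <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    d2 <- (sy - i)^2 + (sx - j)^2
    lab[i, j] <- which.min(d2)
  }
  # renumber by first occurrence so labels are contiguous 1..R
  u <- unique(as.vector(lab))
  matrix(match(as.vector(lab), u), h, w)
}

# spatially correlated standard-normal field(s): T draws, exponential kernel
gaussian_random_fields <- function(h, w, n_t, corr_length) {
  p <- h * w
  z <- matrix(stats::rnorm(n_t * p), n_t, p)
  if (corr_length <= 0) return(z)
  idx <- as.matrix(expand.grid(row = seq_len(h), col = seq_len(w)))
  dmat <- as.matrix(stats::dist(idx))
  k <- exp(-dmat / corr_length)
  cl <- chol(k + diag(1e-10, p))
  z %*% cl
}

#' Generate a synthetic NDVI + climate dataset with planted structure
#'
#' Simulates growing-season monthly grids for NDVI, temperature (TEM),
#' precipitation (PRE) and shortwave radiation (RAD). Climate variables are
#' a seasonal cycle plus linear trend plus spatially correlated Gaussian
#' anomalies. The NDVI anomaly at pixel p follows
#' `a_t = sum_k beta_k z_k(p,t) + m_r(t) + rho a_{t-1} + eps_t`,
#' where `z_k` are the standardized climate anomalies, `m_r` is the
#' region-specific temporal mode, and `eps` is Gaussian innovation noise;
#' the chain starts from its stationary distribution. NDVI values are the
#' anomaly plus region baseline, seasonal cycle and linear trend.
#'
#' @param config a [synth_config()].
#' @return list with elements `ndvi`, `tem`, `pre`, `rad` (each a
#'   [grid_ts()]) and `truth`, a `synth_truth` object holding
#'   `region_labels`, `coupling_matrix`, `planted_trends` and
#'   `dominant_driver` (argmax of `|beta|`; ties resolved to the lowest
#'   variable index, TEM < PRE < RAD).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config"))
    stop("`config` must be a synth_config", call. = FALSE)
  cf <- config
  h <- cf$grid_height; w <- cf$grid_width; p <- h * w
  mpy <- cf$months_per_year; ny <- cf$n_years; nt <- ny * mpy

  with_seed(cf$rng_seed, {
    labels <- switch(cf$partition_mode,
                     blocks = partition_blocks(h, w, cf$n_regions),
                     voronoi = partition_voronoi(h, w, cf$n_regions))
    storage.mode(labels) <- "integer"
    labv <- as.vector(labels)

    months <- cf$start_month + seq_len(mpy) - 1L
    time <- data.frame(year = rep(cf$start_year + seq_len(ny) - 1L, each = mpy),
                       month = rep(months, ny))
    # fractional year at each time step (mid-month), drives linear trends
    tyear <- rep(seq_len(ny) - 1L, each = mpy) +
      (rep(seq_len(mpy), ny) - 0.5) / mpy
    # half-sine seasonal shape over the growing season, peak mid-season
    cyc <- sin(pi * (rep(seq_len(mpy), ny) - 0.5) / mpy)

    zfields <- list()
    clim <- list()
    for (v in c("TEM", "PRE", "RAD")) {
      cv <- cf$climate[[v]]
      z <- gaussian_random_fields(h, w, nt, cv$corr_length)  # unit variance
      zfields[[v]] <- z
      vals <- cv$mean + cv$seasonal_amplitude * cyc + cv$trend * tyear
      clim[[v]] <- array(rep(vals, p), c(nt, h, w)) +
        array(cv$anomaly_sd * z, c(nt, h, w))
    }

    # region-specific temporal anomaly modes, independent across regions
    modes <- matrix(stats::rnorm(nt * cf$n_regions), nt, cf$n_regions)
    modes <- sweep(modes, 2L, cf$region_mode_sd[seq_len(cf$n_regions)], "*")

    rho <- cf$ar1_rho[labv]
    nsd <- cf$noise_sd[labv]
    forcing <- matrix(0, nt, p)
    for (k in 1:3)
      forcing <- forcing + outer(rep(1, nt), cf$beta[labv, k]) * zfields[[k]]
    forcing <- forcing + modes[, labv, drop = FALSE]
    anom <- matrix(0, nt, p)
    eps <- matrix(stats::rnorm(nt * p), nt, p)
    # stationary start for the noise-driven AR(1) part
    anom[1L, ] <- forcing[1L, ] + eps[1L, ] * nsd / sqrt(1 - rho^2)
    if (nt > 1L) for (t in 2:nt)
      anom[t, ] <- forcing[t, ] + rho * anom[t - 1L, ] + eps[t, ] * nsd

    base <- cf$ndvi_base[labv]
    amp <- cf$seasonal_amplitude[labv]
    trd <- cf$trend[labv]
    ndvi <- outer(rep(1, nt), base) + outer(cyc, amp) + outer(tyear, trd) + anom

    lat <- 30 + (seq_len(h) - 0.5) / 12   # 1/12 degree cells, arbitrary origin
    lon <- 100 + (seq_len(w) - 0.5) / 12
    mk <- function(m, role) grid_ts(array(m, c(nt, h, w)), time, lat, lon,
                                    role = role)
    truth <- new_synth_truth(labels, cf$beta, cf$trend, cf$region_mode_sd)
    list(ndvi = mk(ndvi, "NDVI"),
         tem = clim_ts(clim$TEM, time, lat, lon, "TEM"),
         pre = clim_ts(clim$PRE, time, lat, lon, "PRE"),
         rad = clim_ts(clim$RAD, time, lat, lon, "RAD"),
         truth = truth)
  })
}

clim_ts <- function(arr, time, lat, lon, role) grid_ts(arr, time, lat, lon, role = role)

new_synth_truth <- function(labels, beta, trends, region_mode_sd) {
  # dominant driver = argmax |beta| per region; tie -> lowest index
  dom <- apply(abs(beta), 1L, function(b) which.max(b))
  structure(list(region_labels = labels,
                 coupling_matrix = beta,
                 planted_trends = as.numeric(trends),
                 region_mode_sd = as.numeric(region_mode_sd),
                 dominant_driver = structure(as.integer(dom),
                                             names = rownames(beta)),
                 driver_names = c("TEM", "PRE", "RAD")),
            class = "synth_truth")
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("<synth_truth> %d regions on a %d x %d grid\n",
              nrow(x$coupling_matrix), nrow(x$region_labels),
              ncol(x$region_labels)))
  cat("dominant drivers:",
      paste(x$driver_names[x$dominant_driver], collapse = ", "), "\n")
  invisible(x)
}

fmt17 <- function(x) sprintf("%.17g", as.numeric(x))

#' Write / read ground truth
#'
#' Serializes a `synth_truth` to a single JSON file. Floating-point values
#' are written with 17 significant digits so the round trip is lossless.
#'
#' @param truth a `synth_truth` as returned by [generate_dataset()].
#' @param path output file path (JSON).
#' @return `write_truth` returns `path` invisibly; `read_truth` returns the
#'   reconstructed `synth_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synth_truth"))
  obj <- list(
    dim = dim(truth$region_labels),
    region_labels = as.integer(truth$region_labels),
    region_names = rownames(truth$coupling_matrix),
    coupling_matrix = fmt17(truth$coupling_matrix),
    coupling_dim = dim(truth$coupling_matrix),
    planted_trends = fmt17(truth$planted_trends),
    region_mode_sd = fmt17(truth$region_mode_sd),
    dominant_driver = as.integer(truth$dominant_driver),
    driver_names = truth$driver_names)
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- matrix(as.integer(obj$region_labels), obj$dim[1L], obj$dim[2L])
  beta <- matrix(as.numeric(obj$coupling_matrix),
                 obj$coupling_dim[1L], obj$coupling_dim[2L],
                 dimnames = list(obj$region_names, obj$driver_names))
  new_synth_truth(labels, beta, as.numeric(obj$planted_trends),
                  as.numeric(obj$region_mode_sd))
}
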