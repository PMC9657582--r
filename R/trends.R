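#' Per-series trend statistics
#'
#' `ols_trend` is the ordinary least-squares slope of value on time;
#' `sen_slope` is the Theil-Sen estimator, the median of all pairwise
#' slopes `(y_j - y_i) / (t_j - t_i)`, `i < j`; `mk_test` is the
#' Mann-Kendall trend test with the standard tie-corrected variance
#' \deqn{Var(S) = [n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)] / 18}
#' and continuity-corrected standard score
#' `Z = (S - sign(S)) / sqrt(Var(S))` (0 when `S = 0`), with a two-sided
#' normal p-value. Missing values are dropped pairwise.
#'
#' @param y numeric series.
#' @param t numeric time coordinate (defaults to `seq_along(y)`).
#' @return `ols_trend` and `sen_slope` return a slope in units of y per
#'   unit t (`NA` with fewer than 3 finite values). `mk_test` returns
#'   `list(s, var_s, z, p)` (`NA`s with fewer than 4 finite values; an
#'   all-tied series gives `z = 0`, `p = 1`).
#' @export
ols_trend <- function(y, t = seq_along(y)) {
  ok <- is.finite(y) & is.finite(t)
  if (sum(ok) < 3L) return(NA_real_)
  y <- y[ok]; t <- t[ok]
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

#' @rdname ols_trend
#' @export
sen_slope <- function(y, t = seq_along(y)) {
  ok <- is.finite(y) & is.finite(t)
  if (sum(ok) < 3L) return(NA_real_)
  y <- y[ok]; t <- t[ok]
  n <- length(y)
  dy <- outer(y, y, "-")
  dt <- outer(t, t, "-")
  low <- lower.tri(dy)            # (j, i) with j > i
  slopes <- dy[low] / dt[low]
  stats::median(slopes[is.finite(slopes)])
}

#' @rdname ols_trend
#' @export
mk_test <- function(y) {
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < 4L) return(list(s = NA_real_, var_s = NA_real_,
                          z = NA_real_, p = NA_real_))
  sgn <- sign(outer(y, y, "-"))
  s <- sum(sgn[lower.tri(sgn)])
  ties <- table(y)
  ties <- ties[ties > 1L]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (var_s <= 0) return(list(s = s, var_s = var_s, z = 0, p = 1))
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  list(s = s, var_s = var_s, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Five-class vegetation change categorization
#'
#' Classifies a (Theil-Sen slope, Mann-Kendall Z) pair into the five
#' standard change classes: significantly improved (`S >= s_th`,
#' `Z >= z_th`), slightly improved (`S >= s_th`, `|Z| < z_th`), stable
#' (`|S| <= s_th`), slightly degraded, significantly degraded
#' (symmetric for negative slopes). The printed class boundaries overlap
#' at `S = +/- s_th`; precedence is: the stable band `|S| <= s_th` wins
#' first, then the sign of S chooses improved vs degraded, then
#' `|Z| >= z_th` with matching sign upgrades to "significantly", otherwise
#' "slightly" (so discordant slope/Z signs fall to "slightly"). This makes
#' the map total: every finite pair receives exactly one label.
#'
#' @param slope_sen Theil-Sen slope(s), units per year.
#' @param z_mk Mann-Kendall Z score(s).
#' @param slope_threshold stable-band half-width (default 0.0005 NDVI/yr).
#' @param z_threshold significance threshold (default 1.96, 95%).
#' @return factor with levels [change_levels()], same length as input.
#' @export
classify_change <- function(slope_sen, z_mk, slope_threshold = 0.0005,
                            z_threshold = 1.96) {
  stopifnot(length(slope_sen) == length(z_mk))
  out <- rep(NA_character_, length(slope_sen))
  fin <- is.finite(slope_sen) & is.finite(z_mk)
  s <- slope_sen[fin]; z <- z_mk[fin]
  lab <- ifelse(abs(s) <= slope_threshold, "stable",
         ifelse(s > 0,
                ifelse(z >= z_threshold, "significantly_improved",
                       "slightly_improved"),
                ifelse(z <= -z_threshold, "significantly_degraded",
                       "slightly_degraded")))
  out[fin] <- lab
  factor(out, levels = change_levels())
}

#' @rdname classify_change
#' @export
change_levels <- function() {
  c("significantly_degraded", "slightly_degraded", "stable",
    "slightly_improved", "significantly_improved")
}

#' Per-pixel trend raster
#'
#' Computes the OLS slope, Theil-Sen slope, Mann-Kendall Z / p and the
#' five-class change category for every valid pixel, by default on the
#' annual growing-season means (one value per year).
#'
#' @param gts a [grid_ts()] of growing-season monthly values.
#' @param on `"annual"` (default; annual GS means) or `"monthly"` (the raw
#'   monthly series, slopes still per year).
#' @param slope_threshold,z_threshold passed to [classify_change()].
#' @return object of class `trend_raster`: list of `(y, x)` matrices
#'   `slope_ols`, `slope_sen`, `z_mk`, `p_value`, and `category` (integer
#'   codes 1-5 with the level names attached), plus the coordinate vectors.
#' @export
trend_raster <- function(gts, on = c("annual", "monthly"),
                         slope_threshold = 0.0005, z_threshold = 1.96) {
  stopifnot(inherits(gts, "grid_ts"))
  on <- match.arg(on)
  if (on == "annual") {
    am <- annual_means(gts)
    vals <- am$values
    tcoord <- am$years
  } else {
    vals <- gts$values
    tcoord <- gts$time$year + (gts$time$month - 0.5) / 12
  }
  d <- dim(vals)
  shp <- d[2:3]
  slope_ols <- slope_sen_m <- z_m <- p_m <- matrix(NA_real_, shp[1L], shp[2L])
  for (i in seq_len(shp[1L])) for (j in seq_len(shp[2L])) {
    if (!gts$valid_mask[i, j]) next
    v <- vals[, i, j]
    slope_ols[i, j] <- ols_trend(v, tcoord)
    slope_sen_m[i, j] <- sen_slope(v, tcoord)
    mk <- mk_test(v)
    z_m[i, j] <- mk$z
    p_m[i, j] <- mk$p
  }
  cat_f <- classify_change(as.vector(slope_sen_m), as.vector(z_m),
                           slope_threshold, z_threshold)
  category <- matrix(as.integer(cat_f), shp[1L], shp[2L])
  attr(category, "levels") <- change_levels()
  structure(list(slope_ols = slope_ols, slope_sen = slope_sen_m,
                 z_mk = z_m, p_value = p_m, category = category,
                 lat = gts$lat, lon = gts$lon, valid_mask = gts$valid_mask),
            class = "trend_raster")
}

#' Zonal summary of trends and change categories
#'
#' For each zone (watershed or sub-region) reports the percentage of valid
#' pixels in each change category, the percentage with increasing /
#' decreasing Theil-Sen slope, and a histogram of a mean-value raster in
#' 0.1-wide bins. Percentages are over valid pixels and sum to 100 per
#' zone.
#'
#' @param trends a [trend_raster()].
#' @param zones integer `(y, x)` matrix of zone codes, aligned with the
#'   trend raster; `NA` pixels are skipped.
#' @param mean_grid optional `(y, x)` matrix of mean annual values to
#'   histogram (e.g. mean GS-NDVI).
#' @return list of `data.table`s: `category_pct` (zone x category),
#'   `trend_sign_pct`, and `mean_bins` (if `mean_grid` given).
#' @export
area_summary <- function(trends, zones, mean_grid = NULL) {
  stopifnot(inherits(trends, "trend_raster"))
  if (!identical(dim(zones), dim(trends$category)))
    stop("`zones` must align with the trend raster", call. = FALSE)
  ok <- trends$valid_mask & !is.na(zones) & !is.na(trends$category)
  z <- zones[ok]
  lv <- change_levels()
  cat_i <- factor(lv[trends$category[ok]], levels = lv)
  tab <- table(zone = z, category = cat_i)
  pct <- 100 * prop.table(tab, 1L)
  category_pct <- data.table::as.data.table(pct)
  data.table::setnames(category_pct, "N", "pct")
  sen <- trends$slope_sen[ok]
  sign_dt <- data.table::data.table(zone = z, sen = sen)
  trend_sign_pct <- sign_dt[, list(pct_increasing = 100 * mean(sen > 0),
                                   pct_decreasing = 100 * mean(sen < 0),
                                   pct_zero = 100 * mean(sen == 0)),
                            by = "zone"]
  trend_sign_pct <- trend_sign_pct[order(trend_sign_pct$zone)]
  out <- list(category_pct = category_pct, trend_sign_pct = trend_sign_pct)
  if (!is.null(mean_grid)) {
    mv <- mean_grid[ok]
    bins <- cut(mv, breaks = seq(floor(min(mv, na.rm = TRUE) * 10) / 10,
                                 ceiling(max(mv, na.rm = TRUE) * 10 + 1e-9) / 10,
                                 by = 0.1), include.lowest = TRUE, right = FALSE)
    btab <- 100 * prop.table(table(zone = z, bin = bins), 1L)
    out$mean_bins <- data.table::as.data.table(btab)
    data.table::setnames(out$mean_bins, "N", "pct")
  }
  out
}
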