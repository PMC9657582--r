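#' Maximum value composite: biweekly to monthly
#'
#' Collapses sub-monthly observations to one value per calendar month per
#' pixel by taking the maximum, the standard technique for suppressing
#' cloud and aerosol contamination in NDVI records. Missing observations
#' are ignored; a month whose observations are all missing stays missing.
#'
#' @param biweekly a [grid_ts()] with >= 1 observation per (year, month).
#' @return monthly [grid_ts()].
#' @export
monthly_mvc <- function(biweekly) {
  stopifnot(inherits(biweekly, "grid_ts"))
  if (nrow(biweekly$time) == 0L) stop("empty time axis", call. = FALSE)
  key <- biweekly$time$year * 100L + biweekly$time$month
  ukey <- unique(key)    # time is sorted, so unique keys are in order
  d <- dim(biweekly$values)
  out <- array(NA_real_, c(length(ukey), d[2L], d[3L]))
  for (i in seq_along(ukey)) {
    sel <- key == ukey[i]
    sl <- biweekly$values[sel, , , drop = FALSE]
    out[i, , ] <- apply(sl, c(2L, 3L), function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  }
  grid_ts(out,
          data.frame(year = ukey %/% 100L, month = ukey %% 100L),
          biweekly$lat, biweekly$lon, biweekly$valid_mask,
          role = biweekly$role, units = biweekly$units)
}

#' Subset a monthly series to the growing season
#'
#' Retains only calendar months in `[start_month, end_month]`; the default
#' April-October window is the usual growing season for mid-latitude
#' watersheds, chosen to exclude winter snow effects.
#'
#' @param monthly a monthly [grid_ts()].
#' @param start_month,end_month inclusive month window, `1 <= start <= end <= 12`.
#' @return [grid_ts()] restricted to the window.
#' @export
growing_season <- function(monthly, start_month = 4L, end_month = 10L) {
  stopifnot(inherits(monthly, "grid_ts"))
  if (start_month < 1 || end_month > 12 || start_month > end_month)
    stop("months must satisfy 1 <= start_month <= end_month <= 12",
         call. = FALSE)
  sel <- monthly$time$month >= start_month & monthly$time$month <= end_month
  grid_ts(monthly$values[sel, , , drop = FALSE], monthly$time[sel, , drop = FALSE],
          monthly$lat, monthly$lon, monthly$valid_mask,
          role = monthly$role, units = monthly$units)
}

#' Mask bare ground by a growing-season NDVI threshold
#'
#' Pixels whose annual growing-season mean NDVI falls below `threshold`
#' are designated bare ground and removed from the valid mask (strictly
#' `< threshold`; a pixel exactly at the threshold is retained). By default
#' the multi-year mean of the annual GS means is compared; `rule =
#' "any-year"` instead masks a pixel if any single year falls below.
#'
#' @param ndvi growing-season monthly NDVI [grid_ts()].
#' @param threshold bare-ground NDVI threshold (default 0.1).
#' @param rule `"mean"` (default) or `"any-year"`.
#' @return [grid_ts()] with the tightened mask; the number of newly masked
#'   pixels is attached as attribute `"n_removed"`.
#' @export
mask_bare_ground <- function(ndvi, threshold = 0.1, rule = c("mean", "any-year")) {
  stopifnot(inherits(ndvi, "grid_ts"))
  rule <- match.arg(rule)
  am <- annual_means(ndvi)
  bare <- if (rule == "mean") {
    apply(am$values, c(2L, 3L), mean) < threshold
  } else {
    apply(am$values, c(2L, 3L), function(v) any(v < threshold))
  }
  bare[is.na(bare)] <- FALSE
  new_mask <- ndvi$valid_mask & !bare
  n_removed <- sum(ndvi$valid_mask) - sum(new_mask)
  if (sum(new_mask) == 0L)
    warning("bare-ground masking removed every pixel", call. = FALSE)
  out <- grid_ts(ndvi$values, ndvi$time, ndvi$lat, ndvi$lon, new_mask,
                 role = ndvi$role, units = ndvi$units)
  attr(out, "n_removed") <- n_removed
  out
}

#' Bilinear regridding onto a target grid
#'
#' Interpolates each time slice from the four surrounding coarse cells
#' (cell-center coordinates). A field linear in latitude and longitude is
#' reproduced exactly. Target points outside the coarse hull are clamped
#' to the nearest edge cell, with a warning.
#'
#' @param coarse a [grid_ts()] on the coarse grid.
#' @param target_lat,target_lon target cell-center coordinate vectors.
#' @return [grid_ts()] on the target grid.
#' @export
resample_bilinear <- function(coarse, target_lat, target_lon) {
  stopifnot(inherits(coarse, "grid_ts"))
  wy <- interp_weights(coarse$lat, target_lat)
  wx <- interp_weights(coarse$lon, target_lon)
  if (attr(wy, "clamped") || attr(wx, "clamped"))
    warning("target points outside the source hull were clamped to the edge",
            call. = FALSE)
  d <- dim(coarse$values)
  out <- array(NA_real_, c(d[1L], length(target_lat), length(target_lon)))
  for (t in seq_len(d[1L]))
    out[t, , ] <- wy %*% coarse$values[t, , ] %*% t(wx)
  grid_ts(out, coarse$time, target_lat, target_lon,
          role = coarse$role, units = coarse$units)
}

# dense (n_target x n_source) linear interpolation weight matrix, clamped ends
interp_weights <- function(src, tgt) {
  n <- length(src)
  w <- matrix(0, length(tgt), n)
  clamped <- FALSE
  for (i in seq_along(tgt)) {
    x <- tgt[i]
    if (x <= src[1L]) {
      w[i, 1L] <- 1; clamped <- clamped || x < src[1L]
    } else if (x >= src[n]) {
      w[i, n] <- 1; clamped <- clamped || x > src[n]
    } else {
      j <- findInterval(x, src)
      f <- (x - src[j]) / (src[j + 1L] - src[j])
      w[i, j] <- 1 - f
      w[i, j + 1L] <- f
    }
  }
  attr(w, "clamped") <- clamped
  w
}
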