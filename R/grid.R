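#' Gridded time series container
#'
#' A `grid_ts` holds one variable on a regular latitude-longitude grid as a
#' `(time, y, x)` array together with calendar stamps, coordinate vectors, a
#' validity mask and the variable's role in the analysis.
#'
#' Coordinates are cell centers in degrees; latitude is normalized to
#' ascending order internally. Masked-out pixels carry `NA` in `values`,
#' never a silent zero.
#'
#' @param values numeric array with dimensions `(time, y, x)`.
#' @param time data frame with integer columns `year`, `month` and optionally
#'   `half` (1 or 2 for biweekly composites); rows must be strictly
#'   increasing in calendar order.
#' @param lat,lon numeric coordinate vectors (degrees, cell centers),
#'   monotone; lengths must match dims 2 and 3 of `values`.
#' @param valid_mask logical `(y, x)` matrix; `NULL` means all valid.
#' @param role one of `"NDVI"`, `"TEM"`, `"PRE"`, `"RAD"`.
#' @param units units string; defaults chosen per role (NDVI dimensionless,
#'   TEM degC, PRE mm/month, RAD W/m2).
#'
#' @return An object of class `grid_ts`.
#' @export
grid_ts <- function(values, time, lat, lon, valid_mask = NULL,
                    role = c("NDVI", "TEM", "PRE", "RAD"), units = NULL) {
  role <- match.arg(role)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a (time, y, x) array", call. = FALSE)
  d <- dim(values)
  time <- as.data.frame(time)
  if (!all(c("year", "month") %in% names(time)))
    stop("`time` must have columns year and month", call. = FALSE)
  time$year <- as.integer(time$year)
  time$month <- as.integer(time$month)
  if ("half" %in% names(time)) time$half <- as.integer(time$half)
  rownames(time) <- NULL
  if (nrow(time) != d[1L])
    stop("time axis length (", nrow(time), ") != dim(values)[1] (", d[1L], ")",
         call. = FALSE)
  if (length(lat) != d[2L] || length(lon) != d[3L])
    stop("coordinate lengths must match value dimensions", call. = FALSE)
  key <- time_key(time)
  if (nrow(time) > 1L && any(diff(key) <= 0))
    stop("`time` must be strictly increasing", call. = FALSE)
  if (length(lat) > 1L && !all(diff(lat) > 0) && !all(diff(lat) < 0))
    stop("`lat` must be monotone", call. = FALSE)
  if (length(lon) > 1L && !all(diff(lon) > 0) && !all(diff(lon) < 0))
    stop("`lon` must be monotone", call. = FALSE)
  if (length(lat) > 1L && all(diff(lat) < 0)) {   # normalize ascending
    lat <- rev(lat)
    values <- values[, rev(seq_len(d[2L])), , drop = FALSE]
    if (!is.null(valid_mask)) valid_mask <- valid_mask[rev(seq_len(d[2L])), , drop = FALSE]
  }
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, d[2L], d[3L])
  storage.mode(valid_mask) <- "logical"
  if (!identical(dim(valid_mask), d[2:3]))
    stop("`valid_mask` must be a (y, x) matrix matching the grid", call. = FALSE)
  if (is.null(units))
    units <- switch(role, NDVI = "1", TEM = "degC", PRE = "mm/month", RAD = "W/m2")
  # masked pixels carry NA, never silent zeros
  if (any(!valid_mask)) {
    bad <- which(!valid_mask, arr.ind = TRUE)
    for (i in seq_len(nrow(bad))) values[, bad[i, 1L], bad[i, 2L]] <- NA_real_
  }
  structure(list(values = values, time = time, lat = as.numeric(lat),
                 lon = as.numeric(lon), valid_mask = valid_mask,
                 role = role, units = units),
            class = "grid_ts")
}

# sortable integer key for a calendar stamp table
time_key <- function(time) {
  half <- if ("half" %in% names(time)) time$half else 1L
  time$year * 1000L + time$month * 10L + half
}

#' @export
print.grid_ts <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_ts> %s [%s]: %d time steps x %d x %d grid\n",
              x$role, x$units, d[1L], d[2L], d[3L]))
  cat(sprintf("  years %d-%d, months %d-%d; %d/%d valid pixels\n",
              min(x$time$year), max(x$time$year),
              min(x$time$month), max(x$time$month),
              sum(x$valid_mask), length(x$valid_mask)))
  invisible(x)
}

#' Annual growing-season means
#'
#' Collapses a monthly series to one value per year: the mean over the
#' months present in each year (typically the growing-season months).
#'
#' @param gts a [grid_ts()].
#' @return list with `years` (integer vector) and `values`
#'   (`(year, y, x)` array of annual means).
#' @export
annual_means <- function(gts) {
  stopifnot(inherits(gts, "grid_ts"))
  years <- sort(unique(gts$time$year))
  d <- dim(gts$values)
  out <- array(NA_real_, c(length(years), d[2L], d[3L]))
  for (i in seq_along(years)) {
    sel <- gts$time$year == years[i]
    out[i, , ] <- apply(gts$values[sel, , , drop = FALSE], c(2L, 3L), mean)
  }
  list(years = years, values = out)
}

# flatten valid pixels to a (time x pixel) matrix; returns pixel index map
flatten_pixels <- function(gts, require_complete = TRUE) {
  d <- dim(gts$values)
  ok <- gts$valid_mask
  if (require_complete) {
    complete <- apply(gts$values, c(2L, 3L), function(v) all(is.finite(v)))
    ok <- ok & complete
  }
  idx <- which(ok, arr.ind = TRUE)   # column-major order, deterministic
  m <- matrix(NA_real_, d[1L], nrow(idx))
  for (p in seq_len(nrow(idx))) m[, p] <- gts$values[, idx[p, 1L], idx[p, 2L]]
  list(matrix = m, pixel_index = idx)
}
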