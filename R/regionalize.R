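#' Deseasonalized anomaly matrix for EOF analysis
#'
#' Extracts every valid pixel's monthly series, removes the per-pixel
#' monthly climatology (the mean of each calendar month across years), and
#' stacks the anomalies into a `(time x pixel)` matrix. Pixels with any
#' missing value in the retained series are excluded. The annual cycle
#' would otherwise dominate the leading mode of the decomposition.
#'
#' @param gs_ndvi growing-season monthly NDVI [grid_ts()].
#' @return list with `anomalies` (time x pixel matrix), `pixel_index`
#'   (pixel x 2 matrix of row/col, column-major order), `months`
#'   (calendar month per time step) and `time`.
#' @export
build_anomaly_matrix <- function(gs_ndvi) {
  stopifnot(inherits(gs_ndvi, "grid_ts"))
  fl <- flatten_pixels(gs_ndvi, require_complete = TRUE)
  n_excluded <- sum(gs_ndvi$valid_mask) - nrow(fl$pixel_index)
  if (n_excluded > 0L)
    message(n_excluded, " pixel(s) with missing months excluded from the anomaly matrix")
  months <- gs_ndvi$time$month
  a <- deseasonalize(fl$matrix, months)
  list(anomalies = a, pixel_index = fl$pixel_index, months = months,
       time = gs_ndvi$time)
}

# subtract the per-column per-calendar-month mean
deseasonalize <- function(m, months) {
  for (mo in unique(months)) {
    sel <- months == mo
    mu <- colMeans(m[sel, , drop = FALSE])
    m[sel, ] <- sweep(m[sel, , drop = FALSE], 2L, mu)
  }
  m
}

# subtract a per-column OLS linear fit against time index
detrend_linear <- function(m) {
  t_ <- seq_len(nrow(m))
  x <- cbind(1, t_ - mean(t_))
  m - x %*% qr.coef(qr(x), m)
}

#' EOF decomposition of an anomaly matrix
#'
#' Singular value decomposition of the `(time x pixel)` anomaly matrix.
#' Eigenvalues are those of the sample covariance structure
#' (`lambda_k = d_k^2 / (N - 1)` with `N` time samples); loadings are
#' scaled so the squared loadings of mode k sum to `lambda_k`, and PC
#' series are standardized, so the input is exactly the product of PC
#' series and loadings.
#'
#' @param anomalies `(time x pixel)` matrix, or the list returned by
#'   [build_anomaly_matrix()].
#' @return object of class `eof_result`: `eigenvalues` (descending),
#'   `explained_fraction`, `cumulative_fraction`, `loadings`
#'   (mode x pixel), `pc_series` (mode x time), `n_samples`, and the
#'   `pixel_index` if one was supplied.
#' @export
eof_decompose <- function(anomalies) {
  pixel_index <- NULL
  if (is.list(anomalies) && !is.null(anomalies$anomalies)) {
    pixel_index <- anomalies$pixel_index
    anomalies <- anomalies$anomalies
  }
  if (nrow(anomalies) < 2L || ncol(anomalies) < 2L)
    stop("anomaly matrix needs >= 2 times and >= 2 pixels", call. = FALSE)
  n <- nrow(anomalies)
  sv <- svd(anomalies)
  lambda <- sv$d^2 / (n - 1)
  total <- sum(lambda)
  frac <- if (total > 0) lambda / total else rep(0, length(lambda))
  structure(list(eigenvalues = lambda,
                 explained_fraction = frac,
                 cumulative_fraction = cumsum(frac),
                 loadings = t(sv$v) * sv$d / sqrt(n - 1),
                 pc_series = t(sv$u) * sqrt(n - 1),
                 n_samples = n,
                 pixel_index = pixel_index),
            class = "eof_result")
}

#' Reconstruct the anomaly matrix from EOF modes
#'
#' @param eof an [eof_decompose()] result.
#' @param modes which modes to use (default all).
#' @return `(time x pixel)` matrix.
#' @export
eof_reconstruct <- function(eof, modes = seq_along(eof$eigenvalues)) {
  t(eof$pc_series[modes, , drop = FALSE]) %*% eof$loadings[modes, , drop = FALSE]
}

#' North's Rule of Thumb margins
#'
#' For eigenvalues `lambda` estimated from `N` samples, the sampling error
#' of mode k is `delta_lambda_k = lambda_k * sqrt(2 / N)` and the spacing
#' is `delta_s_k = lambda_k - lambda_{k+1}`. A mode is well separated from
#' the next iff `delta_s - delta_lambda > 0`.
#'
#' @param lambda eigenvalues, descending.
#' @param n_samples effective sample count N.
#' @return numeric vector of margins `delta_s - delta_lambda`, one per mode
#'   (the last mode is compared against 0).
#' @export
north_margin <- function(lambda, n_samples) {
  spacing <- lambda - c(lambda[-1L], 0)
  spacing - lambda * sqrt(2 / n_samples)
}

#' Retain EOF modes by cumulative variance and North's Rule of Thumb
#'
#' Retains the first K modes whose cumulative explained variance reaches
#' `cum_threshold`. Each retained mode's separation from the next is
#' checked with North's Rule of Thumb; the cumulative-variance target
#' governs, and retained modes that are not well separated trigger a
#' warning rather than truncation.
#'
#' @param eof an [eof_decompose()] result.
#' @param cum_threshold cumulative explained-variance target in (0, 1].
#' @return list with `n_retained`, `north_margin` (per retained mode),
#'   `separated` (logical per retained mode), `cumulative` (fraction
#'   reached) and a `variance_table` `data.table` (mode, pct of variance,
#'   cumulative pct, margin).
#' @export
retain_by_north <- function(eof, cum_threshold = 0.85) {
  stopifnot(inherits(eof, "eof_result"), cum_threshold > 0, cum_threshold <= 1)
  cum <- eof$cumulative_fraction
  k <- which(cum >= cum_threshold - 1e-12)[1L]
  if (is.na(k)) k <- length(cum)
  margins <- north_margin(eof$eigenvalues, eof$n_samples)[seq_len(k)]
  separated <- margins > 0
  if (any(!separated))
    warning(sum(!separated), " retained mode(s) are not well separated by ",
            "North's Rule of Thumb", call. = FALSE)
  vt <- data.table::data.table(
    mode = seq_len(k),
    pct_variance = 100 * eof$explained_fraction[seq_len(k)],
    cumulative_pct = 100 * cum[seq_len(k)],
    north_margin = margins)
  list(n_retained = k, north_margin = margins, separated = separated,
       cumulative = cum[k], variance_table = vt)
}

#' Varimax rotation of retained EOF loadings
#'
#' Applies an orthogonal Varimax rotation (Kaiser row normalization by
#' default, convergence 1e-10) to the retained loading vectors, returning
#' the rotated loading vectors (RLVs), the rotation matrix, and the pixel
#' of maximum absolute loading per rotated mode, which seed the subsequent
#' clustering.
#'
#' @param loadings `(mode x pixel)` matrix of retained loadings, or an
#'   [eof_decompose()] result plus `n_retained`.
#' @param n_retained number of leading modes to rotate (required when
#'   `loadings` is an `eof_result`).
#' @param normalize Kaiser row normalization (default TRUE).
#' @return object of class `rotated_eof`: `rlv` (mode x pixel), `rotation`
#'   (orthonormal), `seed_pixels` (pixel column index of max |RLV| per
#'   mode), `n_retained`, and `pixel_index` when available.
#' @export
varimax_rotate <- function(loadings, n_retained = NULL, normalize = TRUE) {
  pixel_index <- NULL
  if (inherits(loadings, "eof_result")) {
    if (is.null(n_retained))
      stop("supply `n_retained` when rotating an eof_result", call. = FALSE)
    pixel_index <- loadings$pixel_index
    loadings <- loadings$loadings[seq_len(n_retained), , drop = FALSE]
  }
  k <- nrow(loadings)
  if (k < 2L) {
    message("single retained mode: identity rotation")
    rlv <- loadings
    rot <- diag(1)
  } else {
    vm <- stats::varimax(t(loadings), normalize = normalize, eps = 1e-10)
    rlv <- t(as.matrix(unclass(vm$loadings)))
    rot <- vm$rotmat
  }
  seeds <- apply(abs(rlv), 1L, which.max)
  structure(list(rlv = rlv, rotation = rot, seed_pixels = as.integer(seeds),
                 n_retained = k, pixel_index = pixel_index),
            class = "rotated_eof")
}

#' Seeded K-means clustering of pixels
#'
#' Lloyd iterations from fixed initial centroids (no random restarts), so
#' the result is deterministic given the features and seeds. Features are
#' typically each pixel's vector of rotated loadings, and seeds the
#' max-|RLV| pixels of the rotated modes.
#'
#' @param features `(pixel x k_feature)` matrix.
#' @param seeds integer vector of seed pixel row indices, one per cluster;
#'   their feature vectors are the initial centroids.
#' @param max_iter maximum Lloyd iterations (default 300).
#' @return integer cluster label per pixel (1..k).
#' @export
kmeans_seeded <- function(features, seeds, max_iter = 300L) {
  features <- as.matrix(features)
  centers <- features[seeds, , drop = FALSE]
  if (anyDuplicated(centers))
    stop("duplicate seed pixels give coincident initial centroids ",
         "(degenerate rotation)", call. = FALSE)
  km <- suppressWarnings(
    stats::kmeans(features, centers = centers, iter.max = max_iter,
                  algorithm = "Lloyd"))
  as.integer(km$cluster)
}

#' Geographic refinement of cluster labels
#'
#' Computes 4-connected (optionally 8-connected) components of each
#' cluster on the grid, splits disjoint components of one cluster into
#' separate region IDs, and merges components smaller than
#' `min_region_pixels` into the neighbouring region with which they share
#' the longest boundary (ties to the lowest region ID). Final labels are
#' renumbered contiguously 1..R in order of first occurrence.
#'
#' @param labels integer `(y, x)` matrix of cluster labels, `NA` where
#'   masked.
#' @param min_region_pixels minimum region size in pixels (default 1 =
#'   no merging).
#' @param connectivity 4 (default) or 8.
#' @param split split disjoint components into separate regions (default
#'   TRUE).
#' @return object of class `region_map`: `labels` (integer matrix, NA
#'   where masked) and `region_table` (`data.table` with region, n_pixels,
#'   bounding box).
#' @export
spatial_refine <- function(labels, min_region_pixels = 1L, connectivity = 4L,
                           split = TRUE) {
  stopifnot(is.matrix(labels), connectivity %in% c(4L, 8L))
  comp <- connected_components(labels, connectivity)
  if (!split) {
    # keep multi-part clusters intact: components of one cluster share an id
    comp <- matrix(match(as.vector(labels), sort(unique(as.vector(labels)))),
                   nrow(labels), ncol(labels))
  }
  comp <- merge_small_components(comp, min_region_pixels, connectivity)
  # renumber by first occurrence (column-major), deterministic
  u <- unique(as.vector(comp))
  u <- u[!is.na(u)]
  relab <- matrix(match(as.vector(comp), u), nrow(comp), ncol(comp))
  region_map(relab)
}

region_map <- function(labels) {
  storage.mode(labels) <- "integer"
  ids <- sort(unique(as.vector(labels)))
  rt <- data.table::rbindlist(lapply(ids, function(r) {
    w <- which(labels == r, arr.ind = TRUE)
    data.table::data.table(region = r, n_pixels = nrow(w),
                           row_min = min(w[, 1L]), row_max = max(w[, 1L]),
                           col_min = min(w[, 2L]), col_max = max(w[, 2L]))
  }))
  structure(list(labels = labels, region_table = rt), class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %d regions, %d labeled pixels\n",
              nrow(x$region_table), sum(!is.na(x$labels))))
  print(x$region_table)
  invisible(x)
}

# label connected components of equal-valued cells; NA cells stay NA
connected_components <- function(labels, connectivity = 4L) {
  h <- nrow(labels); w <- ncol(labels)
  comp <- matrix(NA_integer_, h, w)
  nb <- if (connectivity == 4L)
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  else
    cbind(rep(c(-1L, 0L, 1L), each = 3L), rep(c(-1L, 0L, 1L), 3L))[-5L, ]
  nextid <- 0L
  for (start in which(!is.na(labels))) {
    if (!is.na(comp[start])) next
    nextid <- nextid + 1L
    val <- labels[start]
    queue <- start
    comp[start] <- nextid
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      ci <- (cur - 1L) %% h + 1L
      cj <- (cur - 1L) %/% h + 1L
      for (q in seq_len(nrow(nb))) {
        ni <- ci + nb[q, 1L]; nj <- cj + nb[q, 2L]
        if (ni < 1L || ni > h || nj < 1L || nj > w) next
        if (is.na(comp[ni, nj]) && !is.na(labels[ni, nj]) &&
            labels[ni, nj] == val) {
          comp[ni, nj] <- nextid
          queue <- c(queue, (nj - 1L) * h + ni)
        }
      }
    }
  }
  comp
}

# boundary length (adjacent pixel pairs) between a component and each neighbour
merge_small_components <- function(comp, min_pixels, connectivity) {
  if (min_pixels <= 1L) return(comp)
  h <- nrow(comp); w <- ncol(comp)
  nb <- if (connectivity == 4L)
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  else
    cbind(rep(c(-1L, 0L, 1L), each = 3L), rep(c(-1L, 0L, 1L), 3L))[-5L, ]
  repeat {
    sizes <- table(as.vector(comp))
    small <- as.integer(names(sizes)[sizes < min_pixels])
    if (!length(small) || length(sizes) <= 1L) break
    # absorb the smallest first (ties: lowest id)
    ord <- order(sizes[as.character(small)], small)
    target <- small[ord[1L]]
    cells <- which(comp == target, arr.ind = TRUE)
    touch <- integer(0)
    for (r in seq_len(nrow(cells))) for (q in seq_len(nrow(nb))) {
      ni <- cells[r, 1L] + nb[q, 1L]; nj <- cells[r, 2L] + nb[q, 2L]
      if (ni < 1L || ni > h || nj < 1L || nj > w) next
      v <- comp[ni, nj]
      if (!is.na(v) && v != target) touch <- c(touch, v)
    }
    if (!length(touch)) break   # isolated by mask: keep as is
    tt <- table(touch)
    best <- as.integer(names(tt)[order(-tt, as.integer(names(tt)))])[1L]
    comp[comp == target] <- best
  }
  comp
}

#' Hybrid REOF + seeded K-means regionalization
#'
#' The full regionalization chain: deseasonalized anomaly matrix, EOF
#' decomposition, mode retention by cumulative variance with North's Rule
#' of Thumb diagnostics, Varimax rotation, K-means clustering of the
#' rotated-loading feature space seeded at the max-|RLV| pixels, and
#' geographic merge/split into contiguous sub-regions. Deterministic:
#' fixed input gives a fixed region map.
#'
#' @param gs_ndvi growing-season monthly NDVI [grid_ts()].
#' @param cum_var cumulative explained-variance target (default 0.85).
#' @param min_region_frac minimum region size as a fraction of valid
#'   pixels (default 0.01).
#' @param connectivity 4 (default) or 8.
#' @param split split disjoint cluster components (default TRUE).
#' @param feature `"rlv"` (default; cluster on rotated loadings) or
#'   `"time-series"` (cluster on standardized pixel anomaly series).
#' @param normalize Kaiser normalization for Varimax (default TRUE).
#' @return a `region_map` with extra fields: `variance_table` (mode,
#'   percent of variance, cumulative percent, North margin), `n_retained`,
#'   `cluster_labels` (pre-refinement K-means labels on the grid), and
#'   `pixel_index`.
#' @export
regionalize_pipeline <- function(gs_ndvi, cum_var = 0.85,
                                 min_region_frac = 0.01,
                                 connectivity = 4L, split = TRUE,
                                 feature = c("rlv", "time-series"),
                                 normalize = TRUE) {
  feature <- match.arg(feature)
  am <- build_anomaly_matrix(gs_ndvi)
  eof <- eof_decompose(am)
  ret <- retain_by_north(eof, cum_var)
  d <- dim(gs_ndvi$valid_mask)
  if (ret$n_retained < 2L) {
    labels <- matrix(NA_integer_, d[1L], d[2L])
    labels[am$pixel_index] <- 1L
    rm_ <- region_map(labels)
    rm_$variance_table <- ret$variance_table
    rm_$n_retained <- ret$n_retained
    rm_$cluster_labels <- labels
    rm_$pixel_index <- am$pixel_index
    return(rm_)
  }
  reof <- varimax_rotate(eof, n_retained = ret$n_retained,
                         normalize = normalize)
  feats <- if (feature == "rlv") t(reof$rlv) else scale(am$anomalies)
  if (feature == "time-series") feats <- t(feats)
  cl <- kmeans_seeded(feats, reof$seed_pixels)
  labels <- matrix(NA_integer_, d[1L], d[2L])
  labels[am$pixel_index] <- cl
  min_px <- max(1L, ceiling(min_region_frac * nrow(am$pixel_index)))
  out <- spatial_refine(labels, min_region_pixels = min_px,
                        connectivity = connectivity, split = split)
  out$variance_table <- ret$variance_table
  out$n_retained <- ret$n_retained
  out$cluster_labels <- labels
  out$pixel_index <- am$pixel_index
  out
}
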