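#' Write / read a gridded time series
#'
#' Grids are stored as a pair of plain-text files: `path` holds the values
#' as a tab-separated table (one row per time step, one column per pixel,
#' column-major pixel order) and `paste0(path, ".json")` holds the
#' coordinates, calendar stamps, mask, role and units. All floating-point
#' numbers are written with 17 significant digits, so the round trip is
#' bit-lossless.
#'
#' @param gts a [grid_ts()].
#' @param path data file path (the `.json` sidecar is derived from it).
#' @return `write_grid` returns `path` invisibly; `read_grid` the
#'   reconstructed [grid_ts()].
#' @export
write_grid <- function(gts, path) {
  stopifnot(inherits(gts, "grid_ts"))
  d <- dim(gts$values)
  m <- matrix(gts$values, d[1L], d[2L] * d[3L])
  ch <- matrix(sprintf("%.17g", m), d[1L], d[2L] * d[3L])
  ch[is.na(m)] <- "NA"
  data.table::fwrite(data.table::as.data.table(ch), path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  meta <- list(dim = d,
               year = gts$time$year, month = gts$time$month,
               lat = fmt17(gts$lat), lon = fmt17(gts$lon),
               valid_mask = as.integer(gts$valid_mask),
               role = gts$role, units = gts$units)
  if ("half" %in% names(gts$time)) meta$half <- gts$time$half
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("metadata sidecar not found: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("dim", "year", "month", "lat", "lon", "role", "units"))
    if (is.null(meta[[f]]))
      stop("grid metadata is missing field `", f, "`", call. = FALSE)
  d <- as.integer(meta$dim)
  m <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric", na.strings = "NA"))
  if (!identical(dim(m), c(d[1L], d[2L] * d[3L])))
    stop("grid value table does not match the declared dimensions",
         call. = FALSE)
  time <- data.frame(year = as.integer(meta$year),
                     month = as.integer(meta$month))
  if (!is.null(meta$half)) time$half <- as.integer(meta$half)
  grid_ts(array(m, d), time,
          as.numeric(meta$lat), as.numeric(meta$lon),
          matrix(as.logical(meta$valid_mask), d[2L], d[3L]),
          role = meta$role, units = meta$units)
}

#' Cross-tabulate vegetation types by region
#'
#' Percentage of each region's pixels in each vegetation class. Rows
#' (regions) sum to 100 over the classes present in that region.
#'
#' @param regions a `region_map` (or an integer label matrix).
#' @param vegtypes categorical `(y, x)` matrix (integer codes or factor
#'   labels), aligned with the region map.
#' @param drop_absent drop classes absent from a region rather than
#'   reporting 0% (default TRUE).
#' @return long-format `data.table` with columns region, vegtype, pct.
#' @export
crosstab_vegetation <- function(regions, vegtypes, drop_absent = TRUE) {
  lab <- if (inherits(regions, "region_map")) regions$labels else regions
  if (!identical(dim(lab), dim(vegtypes)))
    stop("vegetation raster is not aligned with the region map",
         call. = FALSE)
  ok <- !is.na(lab) & !is.na(vegtypes)
  tab <- table(region = lab[ok], vegtype = vegtypes[ok])
  pct <- 100 * prop.table(tab, 1L)
  out <- data.table::as.data.table(pct)
  data.table::setnames(out, "N", "pct")
  if (drop_absent) out <- out[out$pct > 0, ]
  out[order(out$region, out$vegtype), ]
}

#' Run configuration
#'
#' Collects every tunable of the end-to-end pipeline with the package
#' defaults: April-October growing season, bare-ground NDVI threshold 0.1,
#' change-class thresholds 0.0005 per year and Z 1.96, cumulative-variance
#' target 0.85, minimum region fraction 0.01, and the synthetic-generator
#' settings.
#'
#' @param seed integer RNG seed for the simulation stage.
#' @param synth named list of overrides for [synth_config()].
#' @param start_month,end_month growing-season window.
#' @param bare_threshold bare-ground NDVI threshold.
#' @param slope_threshold,z_threshold change-class thresholds.
#' @param cum_var cumulative explained-variance target.
#' @param min_region_frac minimum region size fraction.
#' @param pc_var predictor variance retained in the weight regression.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, synth = list(),
                       start_month = 4L, end_month = 10L,
                       bare_threshold = 0.1,
                       slope_threshold = 0.0005, z_threshold = 1.96,
                       cum_var = 0.85, min_region_frac = 0.01,
                       pc_var = 0.95) {
  structure(list(seed = as.integer(seed), synth = synth,
                 start_month = as.integer(start_month),
                 end_month = as.integer(end_month),
                 bare_threshold = bare_threshold,
                 slope_threshold = slope_threshold,
                 z_threshold = z_threshold, cum_var = cum_var,
                 min_region_frac = min_region_frac, pc_var = pc_var),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with any subset of the `run_config` fields.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Simulates a dataset (or loads one), then runs preprocessing, trend
#' detection, regionalization, the VSI and the summary tables, writing
#' every artifact plus a checksum manifest to `out_dir`. Two runs with the
#' same config and seed produce bit-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param inputs optional named list of pre-made grids (`ndvi`, `tem`,
#'   `pre`, `rad`, optionally `truth`); when omitted, data are simulated
#'   from `config$synth` with `config$seed`.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest `data.table` (file, md5).
#' @export
run_pipeline <- function(config, out_dir, inputs = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) message("[vegsense] ", sprintf(...))
  t0 <- Sys.time()

  if (is.null(inputs)) {
    scf <- do.call(synth_config, utils::modifyList(config$synth,
                                                   list(rng_seed = config$seed)))
    log_line("simulate: %dx%d grid, %d years x %d months, %d regions",
             scf$grid_height, scf$grid_width, scf$n_years,
             scf$months_per_year, scf$n_regions)
    inputs <- generate_dataset(scf)
  }

  # preprocess
  gs <- growing_season(inputs$ndvi, config$start_month, config$end_month)
  gs <- mask_bare_ground(gs, config$bare_threshold)
  n_valid <- sum(gs$valid_mask)
  log_line("preprocess: %d valid pixels after bare-ground mask (%d removed)",
           n_valid, attr(gs, "n_removed"))
  if (n_valid == 0L)
    stop("preprocess: no valid pixels remain after bare-ground masking",
         call. = FALSE)
  clim <- lapply(inputs[c("tem", "pre", "rad")], growing_season,
                 config$start_month, config$end_month)

  # trends
  tr <- trend_raster(gs, slope_threshold = config$slope_threshold,
                     z_threshold = config$z_threshold)
  log_line("trends: %d pixels classified", sum(!is.na(tr$category)))

  # regionalize
  rg <- regionalize_pipeline(gs, cum_var = config$cum_var,
                             min_region_frac = config$min_region_frac)
  log_line("regionalize: %d modes retained, %d sub-regions",
           rg$n_retained, nrow(rg$region_table))

  # vsi
  vs <- vsi_pipeline(gs, clim$tem, clim$pre, clim$rad, pc_var = config$pc_var)
  log_line("vsi: %d pixels scored", length(vs$vsi))

  # summaries
  mean_grid <- apply(annual_means(gs)$values, c(2L, 3L), mean)
  area <- area_summary(tr, rg$labels, mean_grid)
  regsum <- region_summary(vs, rg, clim$tem, clim$pre, clim$rad)

  # write artifacts
  fp <- function(f) file.path(out_dir, f)
  write_grid(gs, fp("gs_ndvi.tsv"))
  if (!is.null(inputs$truth)) write_truth(inputs$truth, fp("truth.json"))
  wm <- function(m) {
    ch <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    ch[is.na(m)] <- "NA"
    ch
  }
  data.table::fwrite(data.table::as.data.table(wm(tr$slope_sen)),
                     fp("trend_sen.tsv"), sep = "\t", col.names = FALSE)
  data.table::fwrite(data.table::as.data.table(wm(tr$z_mk)),
                     fp("trend_z.tsv"), sep = "\t", col.names = FALSE)
  data.table::fwrite(data.table::as.data.table(tr$category),
                     fp("change_category.tsv"), sep = "\t", col.names = FALSE)
  data.table::fwrite(data.table::as.data.table(rg$labels),
                     fp("region_labels.tsv"), sep = "\t", col.names = FALSE)
  data.table::fwrite(rg$variance_table, fp("variance_table.csv"))
  data.table::fwrite(area$category_pct, fp("category_pct.csv"))
  data.table::fwrite(regsum, fp("region_summary.csv"))
  data.table::fwrite(data.table::as.data.table(wm(vs$grids$vsi)),
                     fp("vsi.tsv"), sep = "\t", col.names = FALSE)
  data.table::fwrite(data.table::as.data.table(vs$grids$dominant),
                     fp("dominant_driver.tsv"), sep = "\t", col.names = FALSE)

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  writeLines(cfg_json, fp("config.json"))
  files <- sort(setdiff(list.files(out_dir), "manifest.csv"))
  manifest <- data.table::data.table(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  data.table::fwrite(manifest, fp("manifest.csv"))
  log_line("done in %.1fs; %d artifacts",
           as.numeric(difftime(Sys.time(), t0, units = "secs")),
           nrow(manifest))
  invisible(list(gs = gs, trends = tr, regions = rg, vsi = vs,
                 area_summary = area, region_summary = regsum,
                 manifest = manifest))
}
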