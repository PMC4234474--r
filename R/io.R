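# Raster and table I/O.
#
# Rasters are written as multi-channel 32-bit TIFF with each band linearly
# rescaled to [0, 1]; a JSON sidecar (<file>.json) carries the pixel size,
# per-band value ranges, band names and the nodata channel flag. Values
# round-trip to single precision (~1e-7 relative). The files are plain
# baseline TIFF, not georeferenced.

#' Write a raster grid (or stack of grids) to TIFF + JSON sidecar
#'
#' @param grids A single `raster_grid` or named list of grids sharing shape
#'   and pixel size (stored as TIFF channels).
#' @param path Output path (`.tif`); the sidecar goes to `paste0(path,
#'   ".json")`.
#' @return `path`, invisibly.
#' @export
write_raster_tif <- function(grids, path) {
  if (is_raster_grid(grids)) grids <- list(band = grids)
  stopifnot(length(grids) >= 1, all(vapply(grids, is_raster_grid, TRUE)))
  if (is.null(names(grids)) || any(names(grids) == ""))
    names(grids) <- paste0("band", seq_along(grids))
  ref <- grids[[1]]
  for (g in grids) check_same_grid(ref, g, "stacked grids")
  nodata <- Reduce(`|`, lapply(grids, function(g) g$nodata_mask))
  has_nodata <- any(nodata)

  ranges <- list()
  chans <- lapply(names(grids), function(nm) {
    v <- grids[[nm]]$values
    if (is.logical(v)) {
      ranges[[nm]] <<- list(lo = 0, hi = 1, logical = TRUE)
      v <- v * 1.0
    } else {
      v[grids[[nm]]$nodata_mask] <- NA
      lo <- suppressWarnings(min(v, na.rm = TRUE))
      hi <- suppressWarnings(max(v, na.rm = TRUE))
      if (!is.finite(lo)) { lo <- 0; hi <- 1 }
      if (hi == lo) hi <- lo + 1
      ranges[[nm]] <<- list(lo = lo, hi = hi, logical = FALSE)
      v <- (v - lo) / (hi - lo)
      v[is.na(v)] <- 0
    }
    v
  })
  if (has_nodata) chans <- c(chans, list(nodata * 1.0))
  arr <- array(unlist(chans), dim = c(nrow(ref$values), ncol(ref$values),
                                      length(chans)))
  suppressWarnings(tiff::writeTIFF(arr, path, bits.per.sample = 32L))
  meta <- list(pixel_size_m = ref$pixel_size_m, bands = names(grids),
               ranges = ranges, has_nodata = has_nodata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster stack written by [write_raster_tif()]
#'
#' @param path Path to the `.tif` file (sidecar expected alongside).
#' @return Named list of `raster_grid`s.
#' @export
read_raster_tif <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) cg_stop("raster file not found: ", path)
  if (!file.exists(sidecar)) cg_stop("raster sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  arr <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  nb <- length(meta$bands)
  nodata <- if (isTRUE(meta$has_nodata)) arr[, , nb + 1L] > 0.5 else
    matrix(FALSE, dim(arr)[1], dim(arr)[2])
  out <- lapply(seq_len(nb), function(i) {
    nm <- meta$bands[i]
    rg <- meta$ranges[[nm]]
    v <- arr[, , i]
    if (isTRUE(rg$logical)) {
      v <- v > 0.5
    } else {
      v <- v * (rg$hi - rg$lo) + rg$lo
      v[nodata] <- NA_real_
    }
    raster_grid(v, meta$pixel_size_m, nodata)
  })
  setNames(out, meta$bands)
}

#' Write a city scene to disk
#'
#' Produces `<dir>/<city_id>_bands.tif` (red + NIR), dito `_impervious.tif`,
#' and `<dir>/<city_id>_meta.json` (population, pixel size).
#'
#' @param scene A [city_scene()].
#' @param dir Output directory (created if needed).
#' @return The metadata path, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "city_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, scene$city_id)
  write_raster_tif(list(red = scene$red, nir = scene$nir),
                   paste0(base, "_bands.tif"))
  write_raster_tif(list(impervious = scene$impervious),
                   paste0(base, "_impervious.tif"))
  meta <- list(city_id = scene$city_id, population = scene$population,
               pixel_size_m = scene$red$pixel_size_m)
  jsonlite::write_json(meta, paste0(base, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(base, "_meta.json"))
}

#' Read a city scene written by [write_scene()]
#'
#' @param dir Directory holding the scene files.
#' @param city_id City identifier.
#' @return A [city_scene()].
#' @export
read_scene <- function(dir, city_id) {
  base <- file.path(dir, city_id)
  missing <- paste0(base, c("_bands.tif", "_impervious.tif", "_meta.json"))
  missing <- missing[!file.exists(missing)]
  if (length(missing))
    cg_stop("missing scene file(s): ", paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(paste0(base, "_meta.json"),
                              simplifyVector = TRUE)
  bands <- read_raster_tif(paste0(base, "_bands.tif"))
  imp <- read_raster_tif(paste0(base, "_impervious.tif"))$impervious
  city_scene(bands$red, bands$nir, imp, meta$population, meta$city_id)
}

#' Write / read the city covariate table
#'
#' Plain CSV with the canonical header (`city_id`, `population`, `hdi`,
#' `di`, `mat_c`, `map_mm`, `hmi`, `koppen`, `lat`, `lon`).
#'
#' @param covariates Covariate data frame.
#' @param path CSV path.
#' @return `path` / the data frame.
#' @export
write_covariates_csv <- function(covariates, path) {
  write.csv(covariates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates_csv
#' @export
read_covariates_csv <- function(path) {
  if (!file.exists(path)) cg_stop("covariate file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("city_id", "population", "hdi", "di", "mat_c", "map_mm", "koppen")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    cg_stop("covariate CSV missing column(s): ",
            paste(missing_cols, collapse = ", "))
  df
}
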