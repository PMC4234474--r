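# Raster data model: lightweight in-memory grids on a square pixel lattice.

#' Create a raster grid
#'
#' A `raster_grid` is a rectangular matrix of values on square pixels of known
#' side length, with an optional nodata mask. It is the basic container for
#' bands, indices and binary masks throughout the package; all per-scene grids
#' are expected to share shape and pixel size.
#'
#' @param values Numeric or logical matrix (rows x cols).
#' @param pixel_size_m Pixel side length in meters (default 30, the Landsat
#'   multispectral resolution the pipeline is designed around).
#' @param nodata_mask Logical matrix of the same shape; `TRUE` cells are
#'   excluded from every statistic. Defaults to all-`FALSE`.
#' @return An object of class `raster_grid` with fields `values`,
#'   `pixel_size_m` and `nodata_mask`.
#' @examples
#' g <- raster_grid(matrix(runif(100), 10, 10))
#' grid_area_m2(raster_grid(matrix(TRUE, 4, 4)))  # 16 pixels x 900 m2
#' @export
raster_grid <- function(values, pixel_size_m = 30, nodata_mask = NULL) {
  if (!is.matrix(values) || (!is.numeric(values) && !is.logical(values)))
    cg_stop("values must be a numeric or logical matrix")
  assert_scalar_num(pixel_size_m, "pixel_size_m", lower = 0, strict_lower = TRUE)
  if (is.null(nodata_mask)) {
    nodata_mask <- matrix(FALSE, nrow(values), ncol(values))
  } else {
    if (!is.logical(nodata_mask) || !identical(dim(nodata_mask), dim(values)))
      cg_stop("nodata_mask must be a logical matrix with the same shape as values")
  }
  structure(list(values = values, pixel_size_m = pixel_size_m,
                 nodata_mask = nodata_mask),
            class = "raster_grid")
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

as_grid_values <- function(x) {
  if (is_raster_grid(x)) x$values else x
}

check_same_grid <- function(a, b, what = "grids") {
  if (!identical(dim(a$values), dim(b$values)))
    cg_stop(what, " have mismatched shapes (",
            paste(dim(a$values), collapse = "x"), " vs ",
            paste(dim(b$values), collapse = "x"), ")")
  if (!isTRUE(all.equal(a$pixel_size_m, b$pixel_size_m)))
    cg_stop(what, " have different pixel sizes")
  invisible(TRUE)
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!x$nodata_mask]
  cat(sprintf("<raster_grid %d x %d, %g m pixels, %d nodata>\n",
              nrow(x$values), ncol(x$values), x$pixel_size_m,
              sum(x$nodata_mask)))
  if (is.logical(x$values)) {
    cat(sprintf("  TRUE: %d (%.1f%%)\n", sum(v), 100 * mean(v)))
  } else {
    cat(sprintf("  range: [%g, %g]\n", suppressWarnings(min(v)),
                suppressWarnings(max(v))))
  }
  invisible(x)
}

#' Total valid area of a binary grid
#'
#' @param grid A logical `raster_grid`.
#' @return Area of `TRUE` pixels in square meters (count x pixel area).
#' @export
grid_area_m2 <- function(grid) {
  stopifnot(is_raster_grid(grid))
  sum(grid$values & !grid$nodata_mask) * grid$pixel_size_m^2
}

#' Bundle the per-city rasters into a scene
#'
#' A `city_scene` holds the red and near-infrared reflectance bands, the
#' binary impervious-surface mask and the city's population — everything the
#' service-extraction chain needs for one city. All grids must share shape and
#' pixel size.
#'
#' @param red,nir Reflectance bands as `raster_grid`s (values >= 0).
#' @param impervious Binary `raster_grid` flagging impervious-surface pixels.
#' @param population Positive number of inhabitants.
#' @param city_id Identifier string.
#' @return Object of class `city_scene`.
#' @export
city_scene <- function(red, nir, impervious, population, city_id = "city") {
  stopifnot(is_raster_grid(red), is_raster_grid(nir), is_raster_grid(impervious))
  check_same_grid(red, nir, "red/nir bands")
  check_same_grid(red, impervious, "bands and impervious mask")
  if (!is.logical(impervious$values))
    cg_stop("impervious mask must be logical")
  assert_scalar_num(population, "population", lower = 0, strict_lower = TRUE)
  structure(list(red = red, nir = nir, impervious = impervious,
                 population = population, city_id = as.character(city_id)),
            class = "city_scene")
}

#' @export
print.city_scene <- function(x, ...) {
  cat(sprintf("<city_scene '%s': %d x %d @ %g m, population %s>\n",
              x$city_id, nrow(x$red$values), ncol(x$red$values),
              x$red$pixel_size_m, format(x$population, big.mark = ",")))
  invisible(x)
}

#' Normalized difference vegetation index
#'
#' Computes per-pixel NDVI = (NIR - red) / (NIR + red), the standard
#' living-vegetation index for red/near-infrared reflectance pairs. Pixels
#' where NIR + red = 0 carry no spectral information and become nodata, as do
#' pixels that are nodata in either input band.
#'
#' @param red,nir `raster_grid`s of nonnegative reflectances with matching
#'   shape and pixel size.
#' @return A `raster_grid` of NDVI values in \[-1, 1\].
#' @examples
#' r <- raster_grid(matrix(0.1, 2, 2)); n <- raster_grid(matrix(0.4, 2, 2))
#' compute_ndvi(r, n)$values[1, 1]  # 0.6
#' @export
compute_ndvi <- function(red, nir) {
  stopifnot(is_raster_grid(red), is_raster_grid(nir))
  check_same_grid(red, nir, "red/nir bands")
  r <- red$values
  n <- nir$values
  if (any(r[!red$nodata_mask] < 0, na.rm = TRUE) ||
      any(n[!nir$nodata_mask] < 0, na.rm = TRUE))
    cg_stop("reflectances must be >= 0")
  tot <- r + n
  nodata <- red$nodata_mask | nir$nodata_mask | (tot == 0)
  ndvi <- (n - r) / tot
  ndvi[nodata] <- NA_real_
  raster_grid(ndvi, red$pixel_size_m, nodata)
}

#' Unsupervised vegetation classification of an NDVI grid
#'
#' Splits an NDVI field into vegetation and non-vegetation. The default
#' `"threshold"` mode flags pixels with NDVI at or above a fixed cut
#' (inclusive, so masks are bit-reproducible); `"kmeans2"` clusters the NDVI
#' values into two groups and takes the higher-mean cluster as vegetation,
#' operationalizing an unsupervised two-class classification without manual
#' photo-interpretation. Cluster seeding is deterministic (initial centers at
#' the 25th and 75th NDVI percentiles). Nodata pixels are never vegetation.
#'
#' @param ndvi `raster_grid` of NDVI in \[-1, 1\].
#' @param method `"threshold"` or `"kmeans2"`.
#' @param threshold NDVI cut for threshold mode (default 0.2, a conventional
#'   green-vegetation cut for 30 m imagery).
#' @return Logical `raster_grid` of vegetation pixels.
#' @export
classify_vegetation <- function(ndvi, method = c("threshold", "kmeans2"),
                                threshold = 0.2) {
  stopifnot(is_raster_grid(ndvi))
  method <- match.arg(method)
  v <- ndvi$values
  ok <- !ndvi$nodata_mask & !is.na(v)
  if (any(v[ok] < -1 - 1e-9) || any(v[ok] > 1 + 1e-9))
    cg_stop("NDVI values must lie in [-1, 1]")
  veg <- matrix(FALSE, nrow(v), ncol(v))
  if (method == "threshold") {
    assert_scalar_num(threshold, "threshold", lower = -1, upper = 1)
    veg[ok] <- v[ok] >= threshold
  } else {
    x <- v[ok]
    if (length(unique(x)) < 2L)
      cg_stop("NDVI is constant; two-cluster classification is degenerate — ",
              "use method = 'threshold' instead",
              class = "citygreen_degenerate_clustering")
    centers <- matrix(unname(quantile(x, c(0.25, 0.75))), ncol = 1)
    if (centers[1] == centers[2]) centers <- matrix(range(x), ncol = 1)
    km <- kmeans(matrix(x, ncol = 1), centers = centers)
    hi <- which.max(km$centers[, 1])
    veg[ok] <- km$cluster == hi
  }
  raster_grid(veg, ndvi$pixel_size_m, ndvi$nodata_mask)
}

#' Thematic accuracy assessment against reference points
#'
#' Builds the predicted-by-reference confusion matrix at a set of reference
#' point locations and reports overall accuracy, per-class user's accuracy
#' (correct / row total, the complement of commission error), producer's
#' accuracy (correct / column total, the complement of omission error) and
#' Cohen's kappa, the chance-corrected agreement
#' kappa = (p_o - p_e) / (1 - p_e) with p_e from the marginal products.
#' With a single class in both margins p_e = 1 and kappa is undefined; it is
#' returned as `NA` with `kappa_defined = FALSE`.
#'
#' @param predicted Logical `raster_grid` (the classification).
#' @param reference_points Data frame with columns `row`, `col` (1-based pixel
#'   indices) and `class` (reference class, coercible to `0`/`1` or
#'   `FALSE`/`TRUE`).
#' @return List of class `cg_accuracy`: `confusion` (predicted x reference),
#'   `overall`, `users`, `producers`, `kappa`, `kappa_defined`, `n`.
#' @export
accuracy_assessment <- function(predicted, reference_points) {
  stopifnot(is_raster_grid(predicted))
  rp <- as.data.frame(reference_points)
  if (!all(c("row", "col", "class") %in% names(rp)))
    cg_stop("reference_points needs columns row, col, class")
  if (nrow(rp) < 2L)
    cg_stop("need at least 2 reference points")
  nr <- nrow(predicted$values); nc <- ncol(predicted$values)
  if (any(rp$row < 1 | rp$row > nr | rp$col < 1 | rp$col > nc))
    cg_stop("reference points out of raster bounds")
  pred <- predicted$values[cbind(rp$row, rp$col)]
  ref <- as.logical(rp$class)
  lv <- c("non-vegetation", "vegetation")
  pf <- factor(lv[pred + 1L], levels = lv)
  rf <- factor(lv[ref + 1L], levels = lv)
  confusion <- table(predicted = pf, reference = rf)
  confusion_metrics(confusion)
}

#' Agreement metrics from a confusion matrix
#'
#' @param confusion Square nonnegative count table, predicted x reference.
#' @return Same structure as [accuracy_assessment()].
#' @export
confusion_metrics <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) cg_stop("confusion matrix must be square")
  if (any(m < 0)) cg_stop("confusion matrix entries must be >= 0")
  total <- sum(m)
  if (total <= 0) cg_stop("confusion matrix total must be > 0")
  diagc <- diag(m)
  overall <- sum(diagc) / total
  users <- ifelse(rowSums(m) > 0, diagc / rowSums(m), NA_real_)
  producers <- ifelse(colSums(m) > 0, diagc / colSums(m), NA_real_)
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  kappa_defined <- pe < 1
  kappa <- if (kappa_defined) (overall - pe) / (1 - pe) else NA_real_
  structure(list(confusion = m, overall = overall, users = users,
                 producers = producers, kappa = kappa,
                 kappa_defined = kappa_defined, n = total),
            class = "cg_accuracy")
}

#' @export
print.cg_accuracy <- function(x, ...) {
  cat("Thematic accuracy assessment (n =", x$n, ")\n")
  print(x$confusion)
  cat(sprintf("overall %.4f | kappa %s\n", x$overall,
              if (x$kappa_defined) sprintf("%.4f", x$kappa) else "undefined"))
  invisible(x)
}
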