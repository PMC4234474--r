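# Per-city ecosystem-service metrics and their cohort-level standardization.

#' Exponential NDVI carbon model
#'
#' Spatially explicit carbon storage per vegetated pixel of the form
#' `carbon_kg(pixel) = a * exp(b * NDVI)`, the widely used exponential fit of
#' Landsat-NDVI to urban vegetation carbon. The coefficients are deliberately
#' parametric: defaults (`a = 1200` kg per 30 m pixel, `b = 3.5`) give
#' urban-realistic magnitudes (on the order of 100 t/ha on vegetated land),
#' and analyses that depend on absolute carbon should supply coefficients
#' calibrated for their imagery.
#'
#' @param a Scale coefficient in kg per pixel (> 0).
#' @param b Unitless NDVI exponent coefficient.
#' @return Object of class `carbon_model`.
#' @export
carbon_model <- function(a = 1200, b = 3.5) {
  assert_scalar_num(a, "a", lower = 0, strict_lower = TRUE)
  assert_scalar_num(b, "b")
  structure(list(a = a, b = b), class = "carbon_model")
}

#' Recreation potential: vegetated area per capita
#'
#' @param veg_area_m2 Vegetated area within the city boundary, in m^2.
#' @param population Number of inhabitants (> 0).
#' @return Recreation potential in m^2 per capita.
#' @examples
#' recreation_potential(8.9e6, 1e6)  # 8.9 m2 per person
#' @export
recreation_potential <- function(veg_area_m2, population) {
  assert_scalar_num(veg_area_m2, "veg_area_m2", lower = 0)
  assert_scalar_num(population, "population", lower = 0, strict_lower = TRUE)
  veg_area_m2 / population
}

#' Carbon storage over a city
#'
#' Sums the exponential NDVI model over vegetation pixels inside the city
#' mask and standardizes the total to tonnes per hectare of city area.
#'
#' @param ndvi NDVI `raster_grid`.
#' @param veg Logical vegetation `raster_grid` on the same grid.
#' @param model [carbon_model()].
#' @param city_mask Logical `raster_grid` of the city extent (default: the
#'   whole raster).
#' @return List with `total_kg` and `t_per_ha` (tonnes per hectare of city
#'   area; `NA` when the city mask is empty).
#' @export
carbon_storage <- function(ndvi, veg, model = carbon_model(),
                           city_mask = NULL) {
  stopifnot(is_raster_grid(ndvi), is_raster_grid(veg),
            inherits(model, "carbon_model"))
  check_same_grid(ndvi, veg, "ndvi/vegetation grids")
  if (is.null(city_mask))
    city_mask <- raster_grid(matrix(TRUE, nrow(ndvi$values), ncol(ndvi$values)),
                             ndvi$pixel_size_m)
  check_same_grid(ndvi, city_mask, "ndvi/city grids")
  sel <- veg$values & city_mask$values & !ndvi$nodata_mask & !veg$nodata_mask
  total_kg <- sum(model$a * exp(model$b * ndvi$values[sel]))
  city_ha <- sum(city_mask$values & !city_mask$nodata_mask) *
    ndvi$pixel_size_m^2 / 1e4
  t_per_ha <- if (city_ha > 0) (total_kg / 1000) / city_ha else NA_real_
  list(total_kg = total_kg, t_per_ha = t_per_ha)
}

#' Configuration for the per-city extraction chain
#'
#' @param classify_method,classify_threshold Vegetation classification mode
#'   (see [classify_vegetation()]).
#' @param buffer_width_m,impervious_threshold Boundary delineation settings
#'   (see [delineate()]).
#' @param mspa [mspa_params()].
#' @param carbon [carbon_model()].
#' @param min_patch_ha Minimum qualifying habitat patch (default 1.44 ha).
#' @param habitat_denominator Denominator mode for [habitat_potential()].
#' @return List of class `profile_config`.
#' @export
profile_config <- function(classify_method = "threshold",
                           classify_threshold = 0.2,
                           buffer_width_m = 200, impervious_threshold = 0.05,
                           mspa = mspa_params(), carbon = carbon_model(),
                           min_patch_ha = 1.44,
                           habitat_denominator = "large_patch_veg") {
  structure(list(classify_method = classify_method,
                 classify_threshold = classify_threshold,
                 buffer_width_m = buffer_width_m,
                 impervious_threshold = impervious_threshold,
                 mspa = mspa, carbon = carbon, min_patch_ha = min_patch_ha,
                 habitat_denominator = habitat_denominator),
            class = "profile_config")
}

#' Full service profile of one city scene
#'
#' Runs the extraction chain — boundary delineation, NDVI, vegetation
#' classification, MSPA segmentation — restricted to the delineated city
#' mask, and computes the three ecosystem services plus green cover. The
#' chain is deterministic given the scene and configuration.
#'
#' @param scene A [city_scene()].
#' @param config A [profile_config()].
#' @return One-row data frame: `city_id`, `population`, `city_area_km2`,
#'   `green_cover_pct`, `recreation_m2_per_capita`, `carbon_t_per_ha`,
#'   `habitat_potential_pct` (`NA` when undefined), `boundary_truncated`.
#' @export
profile_city <- function(scene, config = profile_config()) {
  stopifnot(inherits(scene, "city_scene"), inherits(config, "profile_config"))
  px <- scene$red$pixel_size_m

  boundary <- withCallingHandlers(
    delineate(scene$impervious, config$buffer_width_m,
              config$impervious_threshold),
    citygreen_truncated_boundary = function(w) invokeRestart("muffleWarning"))
  city <- boundary$city_mask

  ndvi <- compute_ndvi(scene$red, scene$nir)
  veg_all <- classify_vegetation(ndvi, config$classify_method,
                                 config$classify_threshold)
  veg <- raster_grid(veg_all$values & city$values, px, veg_all$nodata_mask)

  n_city <- sum(city$values)
  n_veg <- sum(veg$values)
  green_cover_pct <- if (n_city > 0) 100 * n_veg / n_city else NA_real_

  recreation <- recreation_potential(n_veg * px^2, scene$population)
  carbon <- carbon_storage(ndvi, veg, config$carbon, city)

  habitat_pct <- NA_real_
  if (n_veg > 0) {
    seg <- mspa_segment(veg, config$mspa)
    patches <- mspa_patch_table(veg, seg)
    hp <- withCallingHandlers(
      habitat_potential(patches, config$min_patch_ha,
                        config$habitat_denominator,
                        urban_area_ha = n_city * px^2 / 1e4),
      citygreen_undefined_habitat = function(w) invokeRestart("muffleWarning"))
    habitat_pct <- 100 * as.numeric(hp)
  }

  data.frame(city_id = scene$city_id,
             population = scene$population,
             city_area_km2 = boundary$area_km2,
             green_cover_pct = green_cover_pct,
             recreation_m2_per_capita = recreation,
             carbon_t_per_ha = carbon$t_per_ha,
             habitat_potential_pct = habitat_pct,
             boundary_truncated = boundary$truncated,
             stringsAsFactors = FALSE)
}

#' Profile every scene of a cohort
#'
#' @param scenes List of [city_scene()] objects.
#' @param config A [profile_config()].
#' @return Data frame with one [profile_city()] row per scene.
#' @export
profile_cohort <- function(scenes, config = profile_config()) {
  do.call(rbind, lapply(scenes, profile_city, config = config))
}

#' Standardize cohort service values
#'
#' The per-area / per-capita / proportion normalizations are already embodied
#' in the profile columns; this adds the cross-city z-scores used by the
#' multivariate analyses, using the sample standard deviation. Undefined
#' (missing) habitat values propagate as `NA` and are excluded pairwise
#' downstream — never coerced to 0. A zero-variance service cannot be scored
#' and is flagged with a warning (its z-scores become `NA`).
#'
#' @param profiles Data frame of city profiles (>= 2 rows), as produced by
#'   [profile_cohort()].
#' @param service_cols Service columns to score.
#' @return `profiles` with added `z_<service>` columns; attribute
#'   `zero_variance` lists any flagged services.
#' @export
standardize_services <- function(profiles,
                                 service_cols = c("recreation_m2_per_capita",
                                                  "carbon_t_per_ha",
                                                  "habitat_potential_pct")) {
  if (nrow(profiles) < 2L) cg_stop("need at least 2 cities to standardize")
  missing_cols <- setdiff(service_cols, names(profiles))
  if (length(missing_cols))
    cg_stop("missing service columns: ", paste(missing_cols, collapse = ", "))
  flagged <- character()
  for (cl in service_cols) {
    x <- profiles[[cl]]
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      flagged <- c(flagged, cl)
      profiles[[paste0("z_", cl)]] <- NA_real_
    } else {
      profiles[[paste0("z_", cl)]] <- (x - mean(x, na.rm = TRUE)) / s
    }
  }
  if (length(flagged))
    cg_warn("zero-variance service(s): ", paste(flagged, collapse = ", "),
            class = "citygreen_zero_variance")
  attr(profiles, "zero_variance") <- flagged
  profiles
}
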