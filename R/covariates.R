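# Socio-political and climatic indicators and their categorical bins.

#' Köppen group to analysis climate class mapping
#'
#' The four analysis classes collapse the Köppen groups: A (tropical moist)
#' -> tropical, B (dry) -> desert, C (moist mid-latitude, mild winters) ->
#' mediterranean, D (moist mid-latitude, cold winters) -> continental.
#'
#' @return Data frame with columns `koppen_group`, `climate_class`,
#'   `description`.
#' @export
koppen_class_table <- function() {
  data.frame(
    koppen_group = c("A", "B", "C", "D"),
    climate_class = c("tropical", "desert", "mediterranean", "continental"),
    description = c("Tropical moist", "Dry climate",
                    "Moist mid latitude with mild winters",
                    "Moist mid latitude with cold winters"),
    stringsAsFactors = FALSE)
}

#' Heat-moisture index
#'
#' An aridity measure combining mean annual temperature (MAT, degrees C) and
#' mean annual precipitation (MAP, mm/yr). Two published arithmetics are
#' offered:
#'
#' * `"literal"` (default): the plain ratio MAT / MAP;
#' * `"annual"`: the annual heat-moisture form (MAT + 10) / (MAP / 1000).
#'
#' Both increase with aridity; the chosen mode is recorded as an attribute so
#' downstream reports can state it.
#'
#' @param mat_c Mean annual temperature in degrees C.
#' @param map_mm Mean annual precipitation in mm (> 0).
#' @param mode `"literal"` or `"annual"`.
#' @return Numeric HMI value(s) with attribute `hmi_mode`.
#' @examples
#' heat_moisture_index(20, 1000)                    # 0.02
#' heat_moisture_index(10, 1000, mode = "annual")   # 20
#' @export
heat_moisture_index <- function(mat_c, map_mm, mode = c("literal", "annual")) {
  mode <- match.arg(mode)
  if (!is.numeric(mat_c) || !is.numeric(map_mm))
    cg_stop("mat_c and map_mm must be numeric")
  if (any(!is.finite(map_mm)) || any(map_mm <= 0))
    cg_stop("map_mm must be > 0")
  out <- switch(mode,
                literal = mat_c / map_mm,
                annual = (mat_c + 10) / (map_mm / 1000))
  structure(out, hmi_mode = mode)
}

#' Assign the four categorical axes of a city covariate table
#'
#' Bins each record on the four axes used for the grouped analyses:
#'
#' * population at 1M / 2M / 6M inhabitants, right-open bins (`[1M, 2M)`
#'   etc., so exactly 1,000,000 falls in "1-2M");
#' * Democracy Index at cutpoints (default 4, 6, 8 — the published banding:
#'   full democracy >= 8, flawed >= 6, hybrid >= 4, else authoritarian);
#' * HDI at cutpoints (default 0.55, 0.7, 0.8 — low / medium / high /
#'   very high);
#' * Köppen group letter via [koppen_class_table()].
#'
#' @param records Data frame with columns `population`, `hdi`, `di`,
#'   `koppen` (Köppen code; its first letter selects the group).
#' @param di_cutpoints,hdi_cutpoints Strictly increasing cut points
#'   (lower bounds of the upper three classes).
#' @param pop_breaks_m Population breaks in inhabitants (default 1e6, 2e6,
#'   6e6).
#' @return `records` with added factor columns `pop_class`
#'   (`<1M`,`1-2M`,`2-6M`,`>6M`), `di_class` (`authoritarian`,`hybrid`,
#'   `flawed`,`full`), `hdi_class` (`low`,`medium`,`high`,`very high`),
#'   `climate_class`.
#' @export
categorize_cities <- function(records, di_cutpoints = c(4, 6, 8),
                              hdi_cutpoints = c(0.55, 0.7, 0.8),
                              pop_breaks_m = c(1e6, 2e6, 6e6)) {
  records <- as.data.frame(records)
  need <- c("population", "hdi", "di", "koppen")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    cg_stop("records missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.unsorted(di_cutpoints, strictly = TRUE) ||
      is.unsorted(hdi_cutpoints, strictly = TRUE) ||
      is.unsorted(pop_breaks_m, strictly = TRUE))
    cg_stop("cutpoints must be strictly increasing")

  records$pop_class <- cut(records$population,
                           breaks = c(-Inf, pop_breaks_m, Inf),
                           labels = c("<1M", "1-2M", "2-6M", ">6M"),
                           right = FALSE)
  records$di_class <- cut(records$di, breaks = c(-Inf, di_cutpoints, Inf),
                          labels = c("authoritarian", "hybrid", "flawed",
                                     "full"),
                          right = FALSE)
  records$hdi_class <- cut(records$hdi, breaks = c(-Inf, hdi_cutpoints, Inf),
                           labels = c("low", "medium", "high", "very high"),
                           right = FALSE)

  kmap <- koppen_class_table()
  grp <- toupper(substr(as.character(records$koppen), 1, 1))
  bad <- !(grp %in% kmap$koppen_group)
  if (any(bad))
    cg_stop("unmappable Koppen code(s): ",
            paste(unique(records$koppen[bad]), collapse = ", "),
            "; accepted groups: ", paste(kmap$koppen_group, collapse = ", "))
  records$climate_class <- factor(
    kmap$climate_class[match(grp, kmap$koppen_group)],
    levels = kmap$climate_class)
  records
}
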