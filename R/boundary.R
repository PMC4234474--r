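# Urban boundary delineation from the impervious-surface mask.
#
# The city limit is taken where a peripheral buffer first drops below a small
# impervious fraction: starting from the dominant impervious component,
# concentric annuli of fixed width are grown outward and the city mask extends
# to the last annulus whose impervious fraction still meets the threshold.

#' Delineate the analysis extent of a city
#'
#' Implements the buffer rule "the first area with less than 5% impervious
#' surface in a 200 m wide buffer at the periphery of the urban area":
#'
#' 1. The seed is the largest connected component (8-connectivity) of the
#'    impervious mask, hole-filled.
#' 2. Successive annuli of width `round(buffer_width_m / pixel_size_m)` pixels
#'    (7 at the 30 m default) are grown by 8-connected (Chebyshev) dilation.
#' 3. Each annulus is scored by its impervious fraction, with nodata pixels
#'    counted as non-impervious. Growth stops at the first annulus whose
#'    fraction falls below `impervious_threshold`; the city mask is the seed
#'    plus all earlier annuli. Growth proceeds outward from the urban core
#'    because that is the only direction in which "first" is well defined.
#'
#' If the rings are exhausted at the raster edge before a clean annulus is
#' found the result is flagged truncated and a warning is raised. The
#' delineated area is monotone non-increasing in `impervious_threshold`
#' (raising the bar stops growth earlier), and re-delineating the impervious
#' mask restricted to an existing result reproduces it.
#'
#' @param impervious Binary `raster_grid` (must contain at least one
#'   impervious pixel).
#' @param buffer_width_m Annulus width in meters (default 200).
#' @param impervious_threshold Minimum impervious fraction for an annulus to
#'   be absorbed into the city (default 0.05).
#' @return List of class `cg_boundary`: `city_mask` (logical `raster_grid`,
#'   connected and hole-filled), `area_km2`, `annulus_trace` (data frame of
#'   ring index, impervious fraction, and whether the ring was included) and
#'   `truncated`.
#' @examples
#' imp <- matrix(FALSE, 60, 60); imp[25:35, 25:35] <- TRUE
#' b <- delineate(raster_grid(imp))
#' b$area_km2
#' @export
delineate <- function(impervious, buffer_width_m = 200,
                      impervious_threshold = 0.05) {
  stopifnot(is_raster_grid(impervious))
  assert_scalar_num(buffer_width_m, "buffer_width_m", lower = 0, strict_lower = TRUE)
  assert_scalar_num(impervious_threshold, "impervious_threshold",
                    lower = 0, upper = 1)
  imp <- impervious$values & !impervious$nodata_mask
  if (!is.logical(impervious$values)) cg_stop("impervious mask must be logical")
  if (!any(imp)) cg_stop("impervious mask is empty; nothing to delineate")

  px <- impervious$pixel_size_m
  ring_w <- max(1L, as.integer(round(buffer_width_m / px)))

  # seed: largest impervious component, hole-filled
  lab <- .cg_label(imp, 8L)
  sizes <- tabulate(lab[lab > 0L])
  seed <- lab == which.max(sizes)
  seed <- fill_holes(seed, bg_connectivity = 4L)

  cheb <- .cg_chebyshev_dist(seed)
  max_d <- max(cheb[is.finite(cheb)])
  mask <- seed
  trace <- list()
  truncated <- TRUE  # until a terminating clean ring is seen
  i <- 0L
  repeat {
    i <- i + 1L
    lo <- (i - 1L) * ring_w
    hi <- i * ring_w
    ring <- cheb > lo & cheb <= hi
    if (!any(ring)) break  # rings exhausted at the raster edge
    frac <- mean(imp[ring])  # nodata already counted as non-impervious
    include <- frac >= impervious_threshold
    trace[[i]] <- data.frame(ring = i, impervious_fraction = frac,
                             included = include)
    if (!include) {
      truncated <- FALSE
      break
    }
    mask <- mask | ring
    if (hi >= max_d) {  # mask has swallowed the whole raster
      break
    }
  }
  # a mask touching the raster edge may have been clipped: flag it too
  if (!truncated &&
      any(mask[1, ], mask[nrow(mask), ], mask[, 1], mask[, ncol(mask)]))
    truncated <- TRUE
  if (truncated)
    cg_warn("city mask reached the raster edge before a clean annulus; ",
            "boundary truncated", class = "citygreen_truncated_boundary")
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(ring = integer(), impervious_fraction = numeric(),
               included = logical())
  city_mask <- raster_grid(mask, px, impervious$nodata_mask)
  structure(list(city_mask = city_mask,
                 area_km2 = sum(mask) * px^2 / 1e6,
                 annulus_trace = trace,
                 truncated = truncated,
                 ring_width_px = ring_w),
            class = "cg_boundary")
}

#' @export
print.cg_boundary <- function(x, ...) {
  cat(sprintf("<cg_boundary: %.3f km2, %d rings evaluated%s>\n", x$area_km2,
              nrow(x$annulus_trace), if (x$truncated) ", TRUNCATED" else ""))
  invisible(x)
}

#' Area of disagreement between two boundaries
#'
#' The magnitude of the discrepancy between a calculated and a reference
#' (e.g. administrative) boundary: the area of the symmetric difference of
#' the two masks, in square kilometers.
#'
#' @param calculated,reference Logical `raster_grid`s on the same grid.
#' @return Discrepancy in km^2 (nonnegative).
#' @export
boundary_discrepancy <- function(calculated, reference) {
  stopifnot(is_raster_grid(calculated), is_raster_grid(reference))
  check_same_grid(calculated, reference, "boundary masks")
  diff <- xor(calculated$values, reference$values)
  sum(diff) * calculated$pixel_size_m^2 / 1e6
}

# Fill holes of a binary mask: background components (given connectivity) not
# touching the raster border are interior and get absorbed.
fill_holes <- function(mask, bg_connectivity = 4L) {
  bg <- !mask
  lab <- .cg_label(bg, bg_connectivity)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  hole <- bg & !(lab %in% border)
  dim(hole) <- dim(mask)
  mask | hole
}
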