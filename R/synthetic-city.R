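# Synthetic single scenes and 100-city cohorts.
#
# The generator emulates the features the extraction chain actually consumes:
# a spatially autocorrelated NDVI field with controllable cover and
# patchiness, a compact impervious urban core with a noisy, progressively
# sparser periphery, and a covariate table whose bins mirror the reference
# cohort's category mix, with plantable effects of governance and population
# on green provision so recovery of known signals can be tested end to end.

#' Specification of one synthetic city scene
#'
#' @param n_rows,n_cols Pixel counts (>= 16).
#' @param pixel_size_m Pixel side length in meters (default 30).
#' @param target_green_fraction Scene-wide green-cover proportion aimed for
#'   after default classification, in \[0, 1\].
#' @param correlation_length_px Gaussian correlation length of the latent
#'   vegetation field in pixels (> 0); larger values give larger, smoother
#'   patches, smaller values a more fragmented mosaic.
#' @param core_radius_px Radius of the dense impervious urban core (> 0).
#' @param impervious_noise_sd Standard deviation (in pixels) of the smooth
#'   jitter applied to the core radius (>= 0).
#' @param suburb_radius_px Outer radius of the mixed suburban zone whose
#'   scattered impervious surface keeps the 5%-buffer rule growing past the
#'   core (default: 36% of the smaller scene dimension, leaving enough
#'   margin for the boundary stage to terminate inside the raster).
#' @param suburb_impervious_frac Impervious density of the suburban zone
#'   (default 0.12).
#' @param veg_suppression Strength with which the impervious mask pushes the
#'   latent vegetation field down (default 1.5 latent-sd units; set to 0 to
#'   make vegetation independent of the urban fabric).
#' @param population Positive number of inhabitants.
#' @param seed Integer seed; identical specs with identical seeds produce
#'   bit-identical scenes.
#' @param city_id Identifier.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(n_rows = 128L, n_cols = 128L, pixel_size_m = 30,
                       target_green_fraction = 0.30,
                       correlation_length_px = 6,
                       core_radius_px = 18, impervious_noise_sd = 1.5,
                       suburb_radius_px = NULL, suburb_impervious_frac = 0.12,
                       veg_suppression = 1.5,
                       population = 1e6, seed = 1L, city_id = "scene") {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) || n_rows < 16 || n_cols < 16)
    cg_stop("n_rows and n_cols must be >= 16")
  assert_scalar_num(pixel_size_m, "pixel_size_m", lower = 0, strict_lower = TRUE)
  assert_scalar_num(target_green_fraction, "target_green_fraction",
                    lower = 0, upper = 1)
  assert_scalar_num(correlation_length_px, "correlation_length_px",
                    lower = 0, strict_lower = TRUE)
  assert_scalar_num(core_radius_px, "core_radius_px", lower = 0,
                    strict_lower = TRUE)
  assert_scalar_num(impervious_noise_sd, "impervious_noise_sd", lower = 0)
  assert_scalar_num(population, "population", lower = 0, strict_lower = TRUE)
  suburb_radius_px <- suburb_radius_px %||% (0.36 * min(n_rows, n_cols))
  assert_scalar_num(suburb_radius_px, "suburb_radius_px", lower = 0)
  assert_scalar_num(suburb_impervious_frac, "suburb_impervious_frac",
                    lower = 0, upper = 1)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_size_m = pixel_size_m,
                 target_green_fraction = target_green_fraction,
                 correlation_length_px = correlation_length_px,
                 core_radius_px = core_radius_px,
                 impervious_noise_sd = impervious_noise_sd,
                 suburb_radius_px = suburb_radius_px,
                 suburb_impervious_frac = suburb_impervious_frac,
                 veg_suppression = veg_suppression,
                 population = population, seed = as.integer(seed),
                 city_id = as.character(city_id)),
            class = "scene_spec")
}

#' Stationary Gaussian random field
#'
#' Zero-mean, unit-variance field with an (approximately) Gaussian
#' correlation function of the given length, generated by spectral smoothing
#' of white noise on the torus. Draws from the current RNG stream.
#'
#' @param n_rows,n_cols Field size.
#' @param correlation_length_px Correlation length in pixels.
#' @return Numeric matrix.
#' @export
gaussian_random_field <- function(n_rows, n_cols, correlation_length_px) {
  w <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (correlation_length_px < 0.25) return(w)
  rd <- pmin(seq_len(n_rows) - 1L, n_rows - (seq_len(n_rows) - 1L))
  cd <- pmin(seq_len(n_cols) - 1L, n_cols - (seq_len(n_cols) - 1L))
  k <- exp(-outer(rd^2, cd^2, "+") / (2 * correlation_length_px^2))
  f <- Re(fft(fft(w) * fft(k), inverse = TRUE)) / (n_rows * n_cols)
  (f - mean(f)) / sd(f)
}

# 3x3 (chebyshev radius 1) morphological closing
closing3 <- function(m) {
  dil <- .cg_chebyshev_dist(m) <= 1
  .cg_chebyshev_dist(!dil) > 1
}

#' Generate a synthetic city scene
#'
#' Builds a Landsat-like two-band scene plus impervious mask from a
#' [scene_spec()]:
#'
#' 1. a latent Gaussian random field with the requested correlation length,
#'    depressed under the impervious fabric (so parks sit between built
#'    areas), is thresholded at the quantile matching the target green
#'    fraction;
#' 2. NDVI is a sharp logistic squash of the latent field centered so the
#'    default classification threshold (NDVI 0.2) falls exactly at that
#'    quantile, plus slight pixel noise — giving a bimodal NDVI field whose
#'    realized green fraction tracks the target;
#' 3. red and NIR reflectances are reconstructed from NDVI at constant total
#'    brightness, so `compute_ndvi()` round-trips exactly;
#' 4. the impervious mask is a disc with smoothly jittered radius, plus
#'    scattered suburban impervious surface out to `suburb_radius_px`,
#'    regularized by a 3x3 morphological closing — one dominant connected
#'    component for the boundary stage.
#'
#' Identical specs (including seed) give bit-identical scenes; the caller's
#' RNG stream is left untouched.
#'
#' @param spec A [scene_spec()].
#' @return A [city_scene()] with attribute `generator_truth` (the planted
#'   green fraction and field parameters).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols
  with_seed(spec$seed, {
    z <- gaussian_random_field(nr, nc, spec$correlation_length_px)

    # impervious fabric: jittered core disc + scattered suburbs, then closing
    ctr <- c((nr + 1) / 2, (nc + 1) / 2)
    dcen <- sqrt(outer((seq_len(nr) - ctr[1])^2, (seq_len(nc) - ctr[2])^2, "+"))
    jitter <- if (spec$impervious_noise_sd > 0)
      spec$impervious_noise_sd * gaussian_random_field(nr, nc, 3) else 0
    core <- dcen <= spec$core_radius_px + jitter
    suburb <- dcen <= spec$suburb_radius_px &
      matrix(runif(nr * nc), nr, nc) < spec$suburb_impervious_frac
    imp <- closing3(core | suburb)

    z_eff <- z - spec$veg_suppression * imp
    g <- spec$target_green_fraction
    q <- if (g <= 0) Inf else if (g >= 1) -Inf else
      unname(quantile(z_eff, 1 - g, type = 7))
    s <- (z_eff - q) / sd(z_eff)
    ndvi <- -0.2 + 0.8 * plogis(s / 0.15) +
      matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
    ndvi <- pmin(pmax(ndvi, -1), 1)

    total <- 0.5
    red <- raster_grid(total * (1 - ndvi) / 2, spec$pixel_size_m)
    nir <- raster_grid(total * (1 + ndvi) / 2, spec$pixel_size_m)
    scene <- city_scene(red, nir,
                        raster_grid(imp, spec$pixel_size_m),
                        spec$population, spec$city_id)
    attr(scene, "generator_truth") <- list(
      target_green_fraction = g,
      correlation_length_px = spec$correlation_length_px,
      latent_threshold = q)
    scene
  })
}

#' Planted covariate effects for the cohort generator
#'
#' Effects enter on log green area per capita (log recreation potential) and
#' on the latent field's correlation length (fragmentation), the two
#' quantities the downstream inference targets. Defaults plant the reference
#' signal structure: democracy raises green provision per capita, population
#' lowers it, and democracy increases fragmentation (shorter correlation
#' length, hence lower habitat potential).
#'
#' @param beta_di_recreation Slope of log recreation per Democracy Index
#'   point (default 0.12).
#' @param beta_logpop_recreation Slope of log recreation per unit log
#'   population (default -0.8).
#' @param beta_di_fragmentation Slope of log correlation length per DI point
#'   (default -0.06; negative = democracies more fragmented).
#' @param noise_sd City-level lognormal noise on recreation (default 0.25).
#' @param frag_noise_sd Noise on log correlation length (default 0.15).
#' @param base_green_fraction Cohort-median green-cover fraction used to
#'   anchor the intercept (default 0.28).
#' @param base_corr_len_px Baseline correlation length (default 6 px).
#' @return List of class `covariate_effects`.
#' @export
covariate_effects <- function(beta_di_recreation = 0.12,
                              beta_logpop_recreation = -0.8,
                              beta_di_fragmentation = -0.06,
                              noise_sd = 0.25, frag_noise_sd = 0.15,
                              base_green_fraction = 0.28,
                              base_corr_len_px = 6) {
  vals <- c(beta_di_recreation, beta_logpop_recreation, beta_di_fragmentation,
            noise_sd, frag_noise_sd, base_green_fraction, base_corr_len_px)
  if (any(!is.finite(vals))) cg_stop("effect sizes must be finite")
  if (noise_sd < 0 || frag_noise_sd < 0) cg_stop("noise sds must be >= 0")
  structure(list(beta_di_recreation = beta_di_recreation,
                 beta_logpop_recreation = beta_logpop_recreation,
                 beta_di_fragmentation = beta_di_fragmentation,
                 noise_sd = noise_sd, frag_noise_sd = frag_noise_sd,
                 base_green_fraction = base_green_fraction,
                 base_corr_len_px = base_corr_len_px),
            class = "covariate_effects")
}

#' Reference category mix for a 100-city cohort
#'
#' The default marginal counts per categorical axis: climate groups
#' 11 tropical / 13 desert / 60 mediterranean / 16 continental; population
#' 11 / 32 / 39 / 18 across the <1M, 1-2M, 2-6M, >6M bins; HDI 45 very high /
#' 19 high / 22 medium / 14 low; Democracy Index 38 full / 32 flawed /
#' 14 hybrid / 16 authoritarian.
#'
#' @return Named list of four named integer vectors.
#' @export
default_category_counts <- function() {
  list(
    climate = c(tropical = 11L, desert = 13L, mediterranean = 60L,
                continental = 16L),
    population = c("<1M" = 11L, "1-2M" = 32L, "2-6M" = 39L, ">6M" = 18L),
    hdi = c("very high" = 45L, high = 19L, medium = 22L, low = 14L),
    di = c(full = 38L, flawed = 32L, hybrid = 14L, authoritarian = 16L))
}

#' Specification of a synthetic city cohort
#'
#' @param n_cities Number of cities (default 100).
#' @param category_counts Named list of per-axis class counts (each must sum
#'   to `n_cities`); see [default_category_counts()]. By default the
#'   reference mix, rescaled by largest remainder when `n_cities != 100`.
#' @param covariate_model A [covariate_effects()].
#' @param scene Named list of [scene_spec()] arguments shared by all cities
#'   (per-city green fraction, correlation length, population and seed are
#'   filled in by the generator).
#' @param seed Cohort seed; city i uses `seed + i`.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cities = 100L,
                        category_counts = NULL,
                        covariate_model = covariate_effects(),
                        scene = list(), seed = 1L) {
  n_cities <- as.integer(n_cities)
  if (n_cities < 2L) cg_stop("n_cities must be >= 2")
  category_counts <- category_counts %||%
    scale_category_counts(default_category_counts(), n_cities)
  stopifnot(inherits(covariate_model, "covariate_effects"))
  need <- c("climate", "population", "hdi", "di")
  if (!all(need %in% names(category_counts)))
    cg_stop("category_counts needs elements: ", paste(need, collapse = ", "))
  for (ax in need) {
    if (sum(category_counts[[ax]]) != n_cities)
      cg_stop("category_counts$", ax, " sums to ",
              sum(category_counts[[ax]]), ", not n_cities = ", n_cities)
  }
  structure(list(n_cities = n_cities, category_counts = category_counts,
                 covariate_model = covariate_model, scene = scene,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# rescale per-axis class counts to a new total by largest remainder
scale_category_counts <- function(counts, n) {
  lapply(counts, function(v) {
    raw <- v * n / sum(v)
    fl <- floor(raw)
    rem <- n - sum(fl)
    if (rem > 0) {
      idx <- order(raw - fl, decreasing = TRUE)[seq_len(rem)]
      fl[idx] <- fl[idx] + 1
    }
    setNames(as.integer(fl), names(v))
  })
}

# per-class value ranges used when drawing covariates within a bin
COVARIATE_BIN_RANGES <- list(
  di = list(full = c(8, 9.8), flawed = c(6, 8), hybrid = c(4, 6),
            authoritarian = c(1.5, 4)),
  hdi = list("very high" = c(0.80, 0.95), high = c(0.70, 0.80),
             medium = c(0.55, 0.70), low = c(0.35, 0.55)),
  population = list("<1M" = c(3e5, 1e6), "1-2M" = c(1e6, 2e6),
                    "2-6M" = c(2e6, 6e6), ">6M" = c(6e6, 2.2e7)),
  climate = list(
    tropical = list(mat = c(22, 28), map = c(1200, 2600), lat = c(0, 23),
                    koppen = c("Af", "Am", "Aw")),
    desert = list(mat = c(15, 30), map = c(60, 350), lat = c(15, 35),
                  koppen = c("BWh", "BSh", "BWk")),
    mediterranean = list(mat = c(9, 18), map = c(350, 900), lat = c(30, 48),
                         koppen = c("Csa", "Cfa", "Cfb")),
    continental = list(mat = c(1, 9), map = c(350, 800), lat = c(42, 60),
                       koppen = c("Dfa", "Dfb", "Dwa"))))

#' Generate a synthetic city cohort
#'
#' Draws the covariate table (class labels assigned by seeded permutation so
#' every axis reproduces its category counts exactly; values uniform within
#' bin ranges, populations log-uniform), plants the covariate effects on log
#' recreation and fragmentation, derives each city's target green fraction
#' and correlation length, and generates the scenes. Per-city seeds are
#' `spec$seed + city index`, so the whole cohort is a pure function of the
#' spec.
#'
#' @param spec A [cohort_spec()].
#' @param generate_scenes If `FALSE`, skip raster generation and return
#'   only covariates and planted truth (fast path for statistical tests).
#' @return List of class `city_cohort`: `scenes` (list of [city_scene()] or
#'   `NULL`), `covariates` (data frame: city_id, population, hdi, di, mat_c,
#'   map_mm, hmi, koppen, lat, lon), `truth` (planted per-city quantities)
#'   and `spec`.
#' @export
generate_cohort <- function(spec, generate_scenes = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cities
  cm <- spec$covariate_model
  sc_args <- spec$scene
  proto <- do.call(scene_spec, sc_args)

  out <- with_seed(spec$seed, {
    draw_axis <- function(counts) sample(rep(names(counts), counts))
    di_class <- draw_axis(spec$category_counts$di)
    hdi_class <- draw_axis(spec$category_counts$hdi)
    pop_class <- draw_axis(spec$category_counts$population)
    climate_class <- draw_axis(spec$category_counts$climate)

    runif_bin <- function(cls, ranges)
      unname(vapply(cls, function(k) runif(1, ranges[[k]][1], ranges[[k]][2]), 0))
    di <- runif_bin(di_class, COVARIATE_BIN_RANGES$di)
    hdi <- runif_bin(hdi_class, COVARIATE_BIN_RANGES$hdi)
    pop <- floor(exp(runif_bin(pop_class,
                               lapply(COVARIATE_BIN_RANGES$population, log))))
    cl <- COVARIATE_BIN_RANGES$climate
    mat_c <- unname(vapply(climate_class, function(k)
      runif(1, cl[[k]]$mat[1], cl[[k]]$mat[2]), 0))
    map_mm <- unname(vapply(climate_class, function(k)
      runif(1, cl[[k]]$map[1], cl[[k]]$map[2]), 0))
    lat <- unname(vapply(climate_class, function(k) {
      a <- runif(1, cl[[k]]$lat[1], cl[[k]]$lat[2])
      if (runif(1) < 0.5) -a else a
    }, 0))
    koppen <- unname(vapply(climate_class, function(k)
      sample(cl[[k]]$koppen, 1), ""))
    lon <- runif(n, -180, 180)

    # planted effects on log green area per capita and on fragmentation
    area_m2 <- as.numeric(proto$n_rows) * proto$n_cols * proto$pixel_size_m^2
    logpop <- log(pop)
    mu <- log(cm$base_green_fraction * area_m2) - mean(logpop) +
      cm$beta_di_recreation * (di - mean(di)) +
      cm$beta_logpop_recreation * (logpop - mean(logpop)) +
      rnorm(n, sd = cm$noise_sd)
    green_fraction <- pmin(pmax(exp(mu) * pop / area_m2, 0.02), 0.85)
    corr_len <- pmin(pmax(exp(log(cm$base_corr_len_px) +
                                cm$beta_di_fragmentation * (di - mean(di)) +
                                rnorm(n, sd = cm$frag_noise_sd)), 1.5), 15)

    city_id <- sprintf("city_%03d", seq_len(n))
    covariates <- data.frame(
      city_id = city_id, population = pop, hdi = hdi, di = di,
      mat_c = mat_c, map_mm = map_mm,
      hmi = as.numeric(heat_moisture_index(mat_c, map_mm)),
      koppen = koppen, lat = lat, lon = lon,
      stringsAsFactors = FALSE, row.names = NULL)
    truth <- data.frame(
      city_id = city_id, planted_log_recreation = mu,
      target_green_fraction = green_fraction,
      correlation_length_px = corr_len,
      scene_seed = spec$seed + seq_len(n),
      stringsAsFactors = FALSE, row.names = NULL)
    list(covariates = covariates, truth = truth)
  })

  scenes <- NULL
  if (generate_scenes) {
    scenes <- lapply(seq_len(n), function(i) {
      args <- sc_args
      args$target_green_fraction <- out$truth$target_green_fraction[i]
      args$correlation_length_px <- out$truth$correlation_length_px[i]
      args$population <- out$covariates$population[i]
      args$seed <- out$truth$scene_seed[i]
      args$city_id <- out$covariates$city_id[i]
      generate_scene(do.call(scene_spec, args))
    })
  }
  structure(list(scenes = scenes, covariates = out$covariates,
                 truth = out$truth, spec = spec),
            class = "city_cohort")
}

#' @export
print.city_cohort <- function(x, ...) {
  cat(sprintf("<city_cohort: %d cities, seed %d, scenes %s>\n",
              x$spec$n_cities, x$spec$seed,
              if (is.null(x$scenes)) "not generated" else "generated"))
  invisible(x)
}
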