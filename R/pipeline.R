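# Orchestration of the stages into reproducible, configured runs:
# simulate (cohort to disk), profile (scenes to service table) and
# synthesize (service + covariate tables to the statistical results bundle).

#' Pipeline configuration
#'
#' A single flat configuration object covering all stages; it round-trips
#' through YAML unchanged, and every output carries its FNV-1a fingerprint
#' so runs can be traced back to their settings.
#'
#' @param seed Master seed for all stochastic stages.
#' @param n_cities Cohort size (default 100).
#' @param n_rows,n_cols Scene dimensions (default 128 x 128).
#' @param pixel_size_m Pixel size in meters (default 30).
#' @param buffer_width_m,impervious_threshold Boundary delineation settings.
#' @param edge_width_px,min_patch_ha MSPA / habitat settings.
#' @param carbon_a,carbon_b Carbon model coefficients.
#' @param classify_method,classify_threshold Vegetation classification.
#' @param habitat_denominator Denominator mode for habitat potential.
#' @param hmi_mode Heat-moisture index arithmetic (`"literal"`/`"annual"`).
#' @param weights_scheme Spatial weights for Moran's I.
#' @param output_dir Where stage outputs are written.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_cities = 100L, n_rows = 128L,
                            n_cols = 128L, pixel_size_m = 30,
                            buffer_width_m = 200, impervious_threshold = 0.05,
                            edge_width_px = 2L, min_patch_ha = 1.44,
                            carbon_a = 1200, carbon_b = 3.5,
                            classify_method = "threshold",
                            classify_threshold = 0.2,
                            habitat_denominator = "large_patch_veg",
                            hmi_mode = "literal",
                            weights_scheme = "inverse_distance",
                            output_dir = "citygreen_run") {
  cfg <- list(seed = as.integer(seed), n_cities = as.integer(n_cities),
              n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              pixel_size_m = pixel_size_m, buffer_width_m = buffer_width_m,
              impervious_threshold = impervious_threshold,
              edge_width_px = as.integer(edge_width_px),
              min_patch_ha = min_patch_ha,
              carbon_a = carbon_a, carbon_b = carbon_b,
              classify_method = classify_method,
              classify_threshold = classify_threshold,
              habitat_denominator = habitat_denominator,
              hmi_mode = hmi_mode, weights_scheme = weights_scheme,
              output_dir = output_dir)
  bad <- c("buffer_width_m", "impervious_threshold", "edge_width_px",
           "min_patch_ha", "carbon_a")
  for (nm in bad) assert_scalar_num(cfg[[nm]], nm, lower = 0)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config)
  fnv1a_hash(yaml::as.yaml(unclass(config)))

config_cohort_spec <- function(config) {
  cohort_spec(n_cities = config$n_cities,
              scene = list(n_rows = config$n_rows, n_cols = config$n_cols,
                           pixel_size_m = config$pixel_size_m),
              seed = config$seed)
}

config_profile <- function(config) {
  profile_config(classify_method = config$classify_method,
                 classify_threshold = config$classify_threshold,
                 buffer_width_m = config$buffer_width_m,
                 impervious_threshold = config$impervious_threshold,
                 mspa = mspa_params(edge_width_px = config$edge_width_px),
                 carbon = carbon_model(config$carbon_a, config$carbon_b),
                 min_patch_ha = config$min_patch_ha,
                 habitat_denominator = config$habitat_denominator)
}

#' Simulate a cohort to disk
#'
#' Generates the synthetic cohort defined by the configuration and writes
#' the scenes (TIFF + sidecars), the covariate CSV, the planted-truth CSV
#' and a manifest (seed, config fingerprint, category counts, package
#' version).
#'
#' @param config A [pipeline_config()].
#' @return The cohort (invisibly).
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config_cohort_spec(config))
  scene_dir <- file.path(config$output_dir, "scenes")
  for (sc in cohort$scenes) write_scene(sc, scene_dir)
  write_covariates_csv(cohort$covariates,
                       file.path(config$output_dir, "covariates.csv"))
  write.csv(cohort$truth, file.path(config$output_dir, "truth.csv"),
            row.names = FALSE)
  cats <- categorize_cities(cohort$covariates)
  manifest <- list(
    seed = config$seed, config_hash = config_hash(config),
    n_cities = config$n_cities,
    category_counts = list(
      climate = as.list(table(cats$climate_class)),
      population = as.list(table(cats$pop_class)),
      hdi = as.list(table(cats$hdi_class)),
      di = as.list(table(cats$di_class))),
    package_version = as.character(utils::packageVersion("citygreen")))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}

#' Profile a simulated cohort into the service table
#'
#' Reads the scenes listed in the covariate table (all missing scene files
#' are reported together before aborting), runs the extraction chain on each
#' and writes `services.csv`.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional in-memory cohort from [run_simulate()] /
#'   [generate_cohort()]; skips the disk read.
#' @return The service table (invisibly).
#' @export
run_profile <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  pconf <- config_profile(config)
  if (is.null(cohort)) {
    covs <- read_covariates_csv(file.path(config$output_dir,
                                          "covariates.csv"))
    scene_dir <- file.path(config$output_dir, "scenes")
    missing <- character()
    for (id in covs$city_id) {
      files <- file.path(scene_dir, paste0(id, c("_bands.tif",
                                                 "_impervious.tif",
                                                 "_meta.json")))
      missing <- c(missing, files[!file.exists(files)])
    }
    if (length(missing))
      cg_stop("missing scene file(s):\n  ", paste(missing, collapse = "\n  "))
    scenes <- lapply(covs$city_id, function(id) read_scene(scene_dir, id))
  } else {
    scenes <- cohort$scenes
  }
  services <- profile_cohort(scenes, pconf)
  services$config_hash <- config_hash(config)
  write.csv(services, file.path(config$output_dir, "services.csv"),
            row.names = FALSE)
  invisible(services)
}

#' Run the statistical battery on a profiled cohort
#'
#' Joins the service and covariate tables on `city_id` (orphans on either
#' side abort with an explicit list), then computes: the KS normality screen
#' per service, the log-transform of recreation, Moran's I per service,
#' the varimax PCA of services + covariates, a Bayesian regression per
#' service on the standardized covariates, ANOVA + Tukey letters per
#' categorical axis and service, and the grouped Spearman synergy matrix.
#' Results are written as a bundle of CSV/JSON files carrying the seed and
#' config fingerprint.
#'
#' @param config A [pipeline_config()].
#' @param services,covariates Optional in-memory tables (skip the disk
#'   read).
#' @return List of class `cg_synthesis` with elements `ks`, `morans`, `pca`,
#'   `bayes`, `anova`, `spearman`, `services` (transformed), `categories`.
#' @export
run_synthesize <- function(config, services = NULL, covariates = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(services))
    services <- read.csv(file.path(config$output_dir, "services.csv"),
                         stringsAsFactors = FALSE)
  if (is.null(covariates))
    covariates <- read_covariates_csv(file.path(config$output_dir,
                                                "covariates.csv"))
  orphans_s <- setdiff(services$city_id, covariates$city_id)
  orphans_c <- setdiff(covariates$city_id, services$city_id)
  if (length(orphans_s) || length(orphans_c))
    cg_stop("city_id mismatch between services and covariates; orphans: ",
            paste(c(orphans_s, orphans_c), collapse = ", "))
  covariates <- covariates[match(services$city_id, covariates$city_id), ]
  covariates$hmi <- as.numeric(heat_moisture_index(covariates$mat_c,
                                                   covariates$map_mm,
                                                   config$hmi_mode))
  cats <- categorize_cities(covariates)

  service_cols <- c("recreation_m2_per_capita", "carbon_t_per_ha",
                    "habitat_potential_pct")

  ks <- lapply(setNames(service_cols, service_cols), function(cl)
    ks_normality(services[[cl]], nsim = 2000L, seed = config$seed))

  transformed <- log_transform_policy(services)

  coords <- covariates[, c("lon", "lat")]
  morans <- lapply(setNames(service_cols, service_cols), function(cl)
    morans_i(transformed[[cl]], coords, scheme = config$weights_scheme))

  pca_vars <- data.frame(
    recreation = transformed$recreation_m2_per_capita,
    carbon = services$carbon_t_per_ha,
    habitat = services$habitat_potential_pct,
    log_population = log(covariates$population),
    hdi = covariates$hdi, di = covariates$di,
    mat = covariates$mat_c, map = covariates$map_mm, hmi = covariates$hmi)
  pca <- pca_varimax(scale(pca_vars))

  X <- scale(pca_vars[, c("log_population", "hdi", "di", "mat", "map",
                          "hmi")])
  bayes <- lapply(setNames(service_cols, service_cols), function(cl) {
    bayes_regression(transformed[[cl]], X, seed = config$seed)
  })

  axes <- c(pop_class = "pop_class", di_class = "di_class",
            climate_class = "climate_class")
  anova <- lapply(axes, function(ax) {
    lapply(setNames(service_cols, service_cols), function(cl)
      anova_tukey(services[[cl]], cats[[ax]]))
  })

  spearman <- spearman_synergies(
    services, cats[, c("pop_class", "di_class", "climate_class")],
    service_cols = service_cols)

  res <- structure(list(ks = ks, morans = morans, pca = pca, bayes = bayes,
                        anova = anova, spearman = spearman,
                        services = transformed, categories = cats,
                        seed = config$seed,
                        config_hash = config_hash(config)),
                   class = "cg_synthesis")
  write_synthesis_bundle(res, config)
  res
}

write_synthesis_bundle <- function(res, config) {
  out <- file.path(config$output_dir, "synthesis")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = res$seed, config_hash = res$config_hash)

  ks_df <- do.call(rbind, lapply(names(res$ks), function(nm)
    data.frame(service = nm, D = res$ks[[nm]]$D, p = res$ks[[nm]]$p)))
  write.csv(ks_df, file.path(out, "ks_normality.csv"), row.names = FALSE)

  mi_df <- do.call(rbind, lapply(names(res$morans), function(nm)
    data.frame(service = nm, I = res$morans[[nm]]$I, Z = res$morans[[nm]]$Z,
               p = res$morans[[nm]]$p)))
  write.csv(mi_df, file.path(out, "morans_i.csv"), row.names = FALSE)

  write.csv(data.frame(variable = rownames(res$pca$loadings),
                       res$pca$loadings, check.names = FALSE),
            file.path(out, "pca_loadings.csv"), row.names = FALSE)

  bayes_list <- lapply(res$bayes, function(b) b$summary)
  jsonlite::write_json(c(meta, list(models = bayes_list)),
                       file.path(out, "bayes_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  anova_rows <- list()
  for (ax in names(res$anova)) for (sv in names(res$anova[[ax]])) {
    a <- res$anova[[ax]][[sv]]
    g <- a$groups
    g$axis <- ax; g$service <- sv; g$r2 <- a$r2; g$p_overall <- a$p
    anova_rows[[length(anova_rows) + 1]] <- g
  }
  write.csv(do.call(rbind, anova_rows), file.path(out, "anova_tukey.csv"),
            row.names = FALSE)

  write.csv(as.data.frame(res$spearman),
            file.path(out, "spearman_synergies.csv"), row.names = FALSE)
  jsonlite::write_json(meta, file.path(out, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' @export
print.cg_synthesis <- function(x, ...) {
  cat("<cg_synthesis> seed", x$seed, "config", x$config_hash, "\n")
  cat("components: ks, morans, pca, bayes, anova, spearman\n")
  invisible(x)
}
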