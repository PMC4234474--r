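# Synthetic scene and cohort generator.

test_that("identical specs with identical seeds give bit-identical scenes", {
  sp <- scene_spec(n_rows = 64, n_cols = 64, seed = 11)
  s1 <- generate_scene(sp)
  s2 <- generate_scene(sp)
  expect_identical(s1$red$values, s2$red$values)
  expect_identical(s1$nir$values, s2$nir$values)
  expect_identical(s1$impervious$values, s2$impervious$values)
  s3 <- generate_scene(scene_spec(n_rows = 64, n_cols = 64, seed = 12))
  expect_false(identical(s1$red$values, s3$red$values))
})

test_that("the generator leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_scene(scene_spec(n_rows = 32, n_cols = 32, seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("zero target green fraction yields an empty vegetation mask", {
  sc <- generate_scene(scene_spec(n_rows = 64, n_cols = 64,
                                  target_green_fraction = 0, seed = 2))
  veg <- classify_vegetation(compute_ndvi(sc$red, sc$nir))
  expect_false(any(veg$values))
})

test_that("realized green fraction tracks the target", {
  sc <- generate_scene(scene_spec(n_rows = 128, n_cols = 128,
                                  target_green_fraction = 0.35, seed = 7))
  veg <- classify_vegetation(compute_ndvi(sc$red, sc$nir))
  expect_gte(mean(veg$values), 0.30)
  expect_lte(mean(veg$values), 0.40)
})

test_that("realized green fraction converges to target with grid size", {
  err <- vapply(c(64, 128, 256), function(n) {
    devs <- vapply(1:3, function(s) {
      sc <- generate_scene(scene_spec(n_rows = n, n_cols = n,
                                      target_green_fraction = 0.4,
                                      seed = 100 + s))
      veg <- classify_vegetation(compute_ndvi(sc$red, sc$nir))
      abs(mean(veg$values) - 0.4)
    }, 0)
    mean(devs)
  }, 0)
  expect_lt(err[1], 0.05)
  expect_lt(err[3], 0.02)
  expect_lt(err[3], err[1] + 0.01)  # no degradation with size
})

test_that("NDVI spatial correlation increases with the correlation length", {
  lag1_cor <- function(m) cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ]))
  sc_rough <- generate_scene(scene_spec(correlation_length_px = 2, seed = 4,
                                        veg_suppression = 0))
  sc_smooth <- generate_scene(scene_spec(correlation_length_px = 10, seed = 4,
                                         veg_suppression = 0))
  nd_r <- compute_ndvi(sc_rough$red, sc_rough$nir)$values
  nd_s <- compute_ndvi(sc_smooth$red, sc_smooth$nir)$values
  expect_gt(lag1_cor(nd_s), lag1_cor(nd_r))
})

test_that("the impervious mask is one dominant connected noisy disc", {
  sc <- generate_scene(scene_spec(seed = 9))
  lab <- citygreen:::.cg_label(sc$impervious$values, 8L)
  sizes <- sort(tabulate(lab[lab > 0]), decreasing = TRUE)
  expect_gt(sizes[1], pi * 18^2)        # at least the core disc
  expect_gt(sizes[1], 10 * sizes[2])    # dominant over suburban blobs
  ctr <- dim(lab) / 2
  expect_true(sc$impervious$values[ctr[1], ctr[2]])
})

test_that("invalid scene specs are rejected", {
  expect_error(scene_spec(n_rows = 8), ">= 16")
  expect_error(scene_spec(target_green_fraction = 1.2), "<=")
  expect_error(scene_spec(correlation_length_px = 0), "> 0")
  expect_error(scene_spec(population = 0), "> 0")
})

test_that("default cohort reproduces the reference category mix", {
  ch <- generate_cohort(cohort_spec(seed = 3), generate_scenes = FALSE)
  cats <- categorize_cities(ch$covariates)
  expect_equal(as.vector(table(cats$di_class)), c(16, 14, 32, 38))
  expect_equal(as.vector(table(cats$pop_class)), c(11, 32, 39, 18))
  expect_equal(as.vector(table(cats$hdi_class)), c(14, 22, 19, 45))
  expect_equal(as.vector(table(cats$climate_class)), c(11, 13, 60, 16))
})

test_that("cohort generation is a pure function of spec and seed", {
  c1 <- generate_cohort(cohort_spec(n_cities = 10, seed = 5),
                        generate_scenes = FALSE)
  c2 <- generate_cohort(cohort_spec(n_cities = 10, seed = 5),
                        generate_scenes = FALSE)
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(c1$truth, c2$truth)
  expect_equal(c1$truth$scene_seed, 5 + 1:10)  # per-city seed rule
})

test_that("category counts must sum to the number of cities", {
  counts <- default_category_counts()
  counts$di["full"] <- 40L
  expect_error(cohort_spec(n_cities = 100, category_counts = counts),
               "sums to")
})

test_that("zero effects and zero noise give a constant latent mean", {
  cm <- covariate_effects(beta_di_recreation = 0, beta_logpop_recreation = 0,
                          beta_di_fragmentation = 0, noise_sd = 0,
                          frag_noise_sd = 0)
  ch <- generate_cohort(cohort_spec(n_cities = 20, covariate_model = cm,
                                    seed = 8), generate_scenes = FALSE)
  expect_equal(diff(range(ch$truth$planted_log_recreation)), 0)
  expect_equal(diff(range(ch$truth$correlation_length_px)), 0)
})

test_that("OLS on the generated cohort recovers the planted effects", {
  # planted slope on log recreation vs DI, 20 replicate seeds at n = 100
  cm <- covariate_effects()  # defaults: beta_di 0.12, beta_logpop -0.8
  misses <- 0L
  for (s in 1:20) {
    ch <- generate_cohort(cohort_spec(seed = 1000 + s, covariate_model = cm),
                          generate_scenes = FALSE)
    fit <- summary(lm(planted_log_recreation ~ di + log(population),
                      data = cbind(ch$truth, ch$covariates)))
    est <- fit$coefficients["di", ]
    if (abs(est["Estimate"] - 0.12) > 3 * est["Std. Error"]) misses <- misses + 1L
  }
  expect_lte(misses, 2L)  # ~3-sigma miss should be rare
})

test_that("scaled category counts preserve the mix for other cohort sizes", {
  counts <- citygreen:::scale_category_counts(default_category_counts(), 25)
  for (ax in counts) expect_equal(sum(ax), 25L)
  expect_equal(as.integer(counts$di["full"]), 10L)  # 38/100 of 25, rounded up
})
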