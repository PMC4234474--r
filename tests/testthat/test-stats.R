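# Statistical battery: KS screen, log policy, Moran's I, PCA, Bayesian
# regression, ANOVA/Tukey letters, Spearman synergies.

test_that("the KS statistic matches the reference Lilliefors statistic", {
  skip_if_not_installed("nortest")
  set.seed(5)
  for (x in list(rnorm(40), rexp(60), runif(25))) {
    ours <- ks_normality(x, nsim = 50, seed = 1)$D
    ref <- unname(nortest::lillie.test(x)$statistic)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("the KS screen rejects a clearly non-normal sample", {
  set.seed(8)
  x <- rexp(500)
  res <- ks_normality(x, nsim = 999, seed = 2)
  expect_lt(res$p, 0.01)
  expect_error(ks_normality(rep(1, 20)), "constant")
  expect_error(ks_normality(rnorm(5)), "at least 8")
})

test_that("log transform hits exact values and applies the zero-offset rule", {
  tab <- data.frame(recreation_m2_per_capita = c(1, exp(1), exp(2)),
                    carbon_t_per_ha = c(7, 7, 7))
  out <- log_transform_policy(tab)
  expect_equal(out$recreation_m2_per_capita, c(0, 1, 2))
  expect_equal(out$carbon_t_per_ha, tab$carbon_t_per_ha)  # untouched

  tab2 <- data.frame(recreation_m2_per_capita = c(0, 0.4, 2))
  out2 <- log_transform_policy(tab2)
  meta <- attr(out2, "log_transform")
  expect_equal(meta$zero_offset, 0.2)  # half the minimum positive value
  expect_equal(out2$recreation_m2_per_capita[1], log(0.2))
  expect_equal(meta$zero_rows, 1L)

  expect_error(log_transform_policy(
    data.frame(recreation_m2_per_capita = c(0, 0))), "all recreation")
})

test_that("Moran's I statistic matches the independent reference", {
  skip_if_not_installed("ape")
  set.seed(31)
  n <- 40
  coords <- data.frame(lon = runif(n, -170, 170), lat = runif(n, -60, 60))
  x <- rnorm(n) + coords$lat / 30
  w <- spatial_weights(coords, row_standardize = TRUE)
  ours <- morans_i(x, coords, weights = w)
  ref <- ape::Moran.I(x, unclass(w))  # ape row-standardizes internally
  expect_equal(ours$I, ref$observed, tolerance = 1e-10)
  expect_equal(ours$expectation, ref$expected, tolerance = 1e-10)
})

test_that("the normality-null variance of I matches Monte Carlo", {
  set.seed(32)
  n <- 25
  coords <- data.frame(lon = runif(n, -90, 90), lat = runif(n, -60, 60))
  w <- spatial_weights(coords)
  theor <- morans_i(rnorm(n), coords, weights = w)
  sims <- vapply(1:3000, function(i)
    morans_i(rnorm(n), coords, weights = w)$I, 0)
  expect_lt(abs(sd(sims) - theor$sd) / theor$sd, 0.10)
  expect_lt(abs(mean(sims) - theor$expectation), 3 * sd(sims) / sqrt(3000))
})

test_that("Moran's I is positive for latitude-clustered values", {
  set.seed(13)
  coords <- data.frame(lon = runif(50, -180, 180), lat = runif(50, -60, 60))
  res <- morans_i(coords$lat, coords)
  expect_gt(res$I, 0)
  expect_lt(res$p, 0.01)
})

test_that("the permutation null of I is centered on -1/(n-1)", {
  set.seed(14)
  n <- 30
  coords <- data.frame(lon = runif(n, -50, 50), lat = runif(n, -50, 50))
  w <- spatial_weights(coords)
  x <- rnorm(n)
  sims <- vapply(1:300, function(i)
    morans_i(sample(x), coords, weights = w)$I, 0)
  expect_lt(abs(mean(sims) - (-1 / (n - 1))), 3 * sd(sims) / sqrt(300))
})

test_that("a checkerboard on a 4-nearest-neighbour grid is negative", {
  gridc <- expand.grid(lon = seq(0, 6), lat = seq(0, 6))
  vals <- (gridc$lon + gridc$lat) %% 2
  res <- morans_i(vals, gridc, scheme = "knn", k = 4)
  expect_lt(res$I, 0)
})

test_that("coincident coordinates are capped with a warning", {
  coords <- data.frame(lon = c(0, 0, 1, 2, 3, 4, 5, 6),
                       lat = c(0, 0, 1, 2, 3, 4, 5, 6))
  expect_warning(w <- spatial_weights(coords),
                 class = "citygreen_coincident_coords")
  expect_true(all(is.finite(w)))
})

test_that("PCA recovers a planted two-factor structure", {
  set.seed(21)
  n <- 300
  f1 <- rnorm(n); f2 <- rnorm(n)
  tab <- data.frame(a1 = f1 + rnorm(n, sd = 0.45),
                    a2 = f1 + rnorm(n, sd = 0.45),
                    a3 = f1 + rnorm(n, sd = 0.45),
                    b1 = f2 + rnorm(n, sd = 0.45),
                    b2 = f2 + rnorm(n, sd = 0.45),
                    b3 = f2 + rnorm(n, sd = 0.45))
  res <- pca_varimax(tab)
  expect_equal(res$n_retained, 2L)
  expect_identical(res$rotation, "varimax")
  blockA <- res$strong[c("a1", "a2", "a3"), ]
  blockB <- res$strong[c("b1", "b2", "b3"), ]
  compA <- which(colSums(blockA) == 3)
  compB <- which(colSums(blockB) == 3)
  expect_length(compA, 1)
  expect_length(compB, 1)
  expect_false(compA == compB)
  expect_false(any(blockA[, compB]) || any(blockB[, compA]))
})

test_that("varimax leaves the retained variance unchanged", {
  set.seed(22)
  n <- 150
  f <- rnorm(n)
  tab <- data.frame(x1 = f + rnorm(n), x2 = f + rnorm(n),
                    x3 = rnorm(n), x4 = f + rnorm(n), x5 = rnorm(n))
  res <- pca_varimax(tab)
  eig <- prcomp(tab, scale. = TRUE)$sdev^2
  expect_equal(sum(res$variance_explained),
               sum(eig[eig > 1]) / ncol(tab), tolerance = 1e-10)
})

test_that("independent variables leave no eigenvalue materially above 1", {
  set.seed(23)
  tab <- as.data.frame(matrix(rnorm(600 * 6), 600, 6))
  res <- pca_varimax(tab)
  expect_lt(max(res$eigenvalues), 1.35)
  expect_gte(res$n_retained, 1L)  # the rule keeps whatever clears 1
})

test_that("PCA input validation", {
  expect_error(pca_varimax(data.frame(a = 1:5, b = 1:5)), "3 variables")
  expect_error(pca_varimax(matrix(rnorm(12), 3, 4)), "fewer")
})

test_that("Bayesian regression recovers a strong planted slope", {
  set.seed(41)
  x <- rnorm(100)
  y <- 2 * x + rnorm(100, sd = 0.1)
  fit <- bayes_regression(y, data.frame(x = x), iterations = 4000,
                          burn_in = 1000, seed = 7)
  s <- fit$summary[fit$summary$coefficient == "x", ]
  expect_lt(abs(s$mean - 2), 3 * s$sd)
  expect_true(s$significant)
  expect_lt(s$rhat, 1.1)
})

test_that("the posterior matches the closed-form flat-prior solution", {
  # flat prior + Jeffreys variance => marginal posterior of beta is a
  # multivariate t centered at the OLS estimate
  set.seed(42)
  n <- 80
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- 1 + 0.5 * X$x1 - 0.3 * X$x2 + rnorm(n, sd = 0.8)
  fit <- bayes_regression(y, X, iterations = 12000, burn_in = 2000, seed = 3)
  ols <- lm(y ~ x1 + x2, data = X)
  bhat <- coef(ols)
  s2 <- sum(resid(ols)^2) / (n - 3)
  scale_sd <- sqrt(diag(s2 * chol2inv(chol(crossprod(cbind(1, as.matrix(X)))))) *
                     (n - 3) / (n - 5))
  expect_equal(unname(fit$summary$mean), unname(bhat), tolerance = 0.02)
  expect_equal(unname(fit$summary$sd), unname(scale_sd), tolerance = 0.06)
})

test_that("MCMC schedule and design-matrix guards fire", {
  x <- rnorm(30); y <- rnorm(30)
  expect_error(bayes_regression(y, data.frame(x = x), iterations = 100,
                                burn_in = 99), "at least 2")
  X <- data.frame(a = x, b = 2 * x)
  expect_error(bayes_regression(y, X, iterations = 100, burn_in = 10),
               "collinear")
})

test_that("ANOVA separates a planted shifted group with its own letter", {
  set.seed(51)
  vals <- c(rnorm(30), rnorm(30), rnorm(30, mean = 3))
  grp <- rep(c("g1", "g2", "g3"), each = 30)
  res <- anova_tukey(vals, grp)
  letters <- setNames(res$groups$letters, res$groups$group)
  expect_false(grepl(letters[["g3"]], letters[["g1"]], fixed = TRUE))
  expect_true(letters[["g1"]] == letters[["g2"]])
  expect_lt(res$p, 1e-6)
  expect_gt(res$r2, 0.3)
})

test_that("two-group ANOVA reduces to the squared t statistic", {
  set.seed(52)
  vals <- c(rnorm(20), rnorm(20, 0.5))
  grp <- rep(c("a", "b"), each = 20)
  res <- anova_tukey(vals, grp)
  tt <- t.test(vals ~ grp, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("compact letters agree with the reference implementation", {
  skip_if_not_installed("multcomp")
  set.seed(53)
  vals <- c(rnorm(25, 0), rnorm(25, 0.6), rnorm(25, 1.2), rnorm(25, 3))
  grp <- factor(rep(paste0("g", 1:4), each = 25))
  res <- anova_tukey(vals, grp)
  fit <- aov(vals ~ grp)
  cld <- multcomp::cld(multcomp::glht(fit, linfct = multcomp::mcp(
    grp = "Tukey")))$mcletters$Letters
  share <- function(letters) {
    outer(letters, letters, Vectorize(function(a, b)
      any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])))
  }
  ours <- setNames(res$groups$letters, res$groups$group)
  expect_identical(unname(share(ours[levels(grp)])),
                   unname(share(cld[levels(grp)])))
})

test_that("undersized groups are dropped with a warning", {
  vals <- c(rnorm(10), rnorm(10, 1), 5)
  grp <- c(rep("a", 10), rep("b", 10), "tiny")
  expect_warning(res <- anova_tukey(vals, grp),
                 class = "citygreen_small_group")
  expect_equal(sort(res$groups$group), c("a", "b"))
})

test_that("Spearman synergies hit the exact rank-correlation values", {
  tab <- data.frame(recreation_m2_per_capita = c(1, 2, 3, 4),
                    carbon_t_per_ha = c(1, 3, 2, 4),
                    habitat_potential_pct = c(4, 3, 2, 1))
  res <- spearman_synergies(tab, min_n = 4)
  rc <- res[res$pair == "recreation_m2_per_capita vs carbon_t_per_ha", ]
  expect_equal(rc$rho, 0.8)  # 1 - 6*2/(4*15)
  rh <- res[res$pair == "recreation_m2_per_capita vs habitat_potential_pct", ]
  expect_equal(rh$rho, -1)
  tab$habitat_potential_pct <- exp(tab$recreation_m2_per_capita)
  res2 <- spearman_synergies(tab, min_n = 4)
  expect_equal(res2$rho[res2$pair ==
    "recreation_m2_per_capita vs habitat_potential_pct"], 1)
})

test_that("Spearman is invariant under monotone transformation", {
  tab <- toy_services(25)
  r1 <- spearman_synergies(tab)
  tab2 <- tab
  tab2$carbon_t_per_ha <- log1p(tab2$carbon_t_per_ha - min(tab2$carbon_t_per_ha))
  r2 <- spearman_synergies(tab2)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
})

test_that("the report star scheme reproduces the unconventional legend", {
  star <- citygreen:::star_label
  expect_equal(star(0.0005, "report"), "***")
  expect_equal(star(0.005, "report"), "*")    # * is p<0.01 in the report
  expect_equal(star(0.03, "report"), "**")    # ** is p<0.05 in the report
  expect_equal(star(0.2, "report"), "")
  expect_equal(star(0.005, "conventional"), "**")
  expect_equal(star(0.03, "conventional"), "*")
})

test_that("small or constant strata are reported NA with warnings", {
  tab <- toy_services(12)
  cats <- data.frame(grp = factor(c(rep("big", 9), rep("small", 3))))
  expect_warning(res <- spearman_synergies(tab, cats),
                 class = "citygreen_small_stratum")
  sm <- res[res$stratum == "small", ]
  expect_true(all(is.na(sm$rho)))
  tab2 <- toy_services(12)
  tab2$carbon_t_per_ha <- 3  # constant in both carbon pairs
  w <- capture_warnings(res2 <- spearman_synergies(tab2))
  expect_true(any(grepl("constant service", w)))
  expect_true(is.na(res2$rho[res2$pair ==
    "recreation_m2_per_capita vs carbon_t_per_ha"]))
})
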