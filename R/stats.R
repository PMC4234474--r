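# The cohort-level statistical battery: normality screening, spatial
# autocorrelation, varimax PCA, Bayesian regression, ANOVA with Tukey HSD
# compact letters, and grouped Spearman synergy/tradeoff matrices.

#' Kolmogorov-Smirnov normality screen with estimated parameters
#'
#' One-sample KS statistic against a normal with mean and sd estimated from
#' the data. Because the parameters are estimated, the classical KS null is
#' wrong (Lilliefors' problem); the p-value is calibrated by seeded
#' Monte-Carlo simulation of the statistic under normal samples of the same
#' size, p = (1 + #\{D_sim >= D_obs\}) / (nsim + 1).
#'
#' @param values Numeric vector, n >= 8, non-constant.
#' @param nsim Monte-Carlo replicates for the null distribution
#'   (default 10000).
#' @param seed Optional seed for the Monte-Carlo draw (the caller's RNG
#'   stream is preserved).
#' @return List: `D`, `p`, `n`, `nsim`.
#' @export
ks_normality <- function(values, nsim = 10000L, seed = NULL) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 8L) cg_stop("need at least 8 finite values")
  if (sd(x) == 0) cg_stop("values are constant; normality screen undefined")
  D <- lilliefors_stat(x)
  sims <- with_seed(seed, {
    vapply(seq_len(nsim), function(i) lilliefors_stat(rnorm(n)), 0)
  })
  p <- (1 + sum(sims >= D)) / (nsim + 1)
  list(D = D, p = p, n = n, nsim = nsim)
}

# sup-distance between the empirical cdf and the normal fitted by moments
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  cdf <- pnorm(z)
  i <- seq_len(n)
  max(i / n - cdf, cdf - (i - 1) / n)
}

#' Log-transform policy for recreation potential
#'
#' Applies the natural log to the recreation column only (the service whose
#' skew violates the analyses' normality assumptions). Zeros are offset to
#' half the minimum positive value before the log, and the offset is
#' recorded. The transformation record is attached as attribute
#' `log_transform` (columns transformed, offset used, indices offset).
#'
#' @param service_table Data frame containing `recreation_m2_per_capita`.
#' @return The table with `recreation_m2_per_capita` replaced by its log and
#'   a `log_transform` attribute.
#' @export
log_transform_policy <- function(service_table) {
  col <- "recreation_m2_per_capita"
  if (!col %in% names(service_table))
    cg_stop("service table lacks column ", col)
  x <- service_table[[col]]
  if (any(x < 0, na.rm = TRUE)) cg_stop("recreation values must be >= 0")
  pos <- x[!is.na(x) & x > 0]
  if (!length(pos)) cg_stop("all recreation values are zero; cannot log-transform")
  zeros <- which(!is.na(x) & x == 0)
  offset <- min(pos) / 2
  if (length(zeros)) x[zeros] <- offset
  service_table[[col]] <- log(x)
  attr(service_table, "log_transform") <- list(
    column = col, scale = "natural log",
    zero_offset = if (length(zeros)) offset else NA_real_,
    zero_rows = zeros)
  service_table
}

#' Spatial weights between cities
#'
#' Builds the symmetric nonnegative weight matrix used by [morans_i()]:
#' inverse great-circle distance (default) or k-nearest-neighbour adjacency,
#' optionally row-standardized afterwards. Coincident city pairs would give
#' infinite inverse-distance weights; they are capped at the largest finite
#' weight with a warning.
#'
#' @param coords Data frame or matrix with columns `lon`, `lat` in degrees.
#' @param scheme `"inverse_distance"` or `"knn"`.
#' @param k Neighbours for the knn scheme (default 4; symmetrized by union).
#' @param row_standardize Scale each row to sum 1 (default `TRUE`).
#' @return Weight matrix with zero diagonal; attribute `scheme`.
#' @export
spatial_weights <- function(coords, scheme = c("inverse_distance", "knn"),
                            k = 4L, row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  coords <- as.data.frame(coords)
  if (!all(c("lon", "lat") %in% names(coords)))
    cg_stop("coords needs columns lon, lat")
  n <- nrow(coords)
  if (n < 2L) cg_stop("need at least 2 locations")
  dm <- geosphere::distm(coords[, c("lon", "lat")]) / 1000  # km
  if (scheme == "inverse_distance") {
    w <- 1 / dm
    diag(w) <- 0
    if (any(!is.finite(w))) {
      cap <- max(w[is.finite(w)])
      w[!is.finite(w)] <- cap
      diag(w) <- 0
      cg_warn("coincident coordinates; pair weight capped at the maximum ",
              "finite weight", class = "citygreen_coincident_coords")
    }
  } else {
    w <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(dm[i, ])[-1][seq_len(min(k, n - 1L))]
      w[i, nb] <- 1
    }
    w <- pmax(w, t(w))  # symmetrize
  }
  if (row_standardize) {
    rs <- rowSums(w)
    rs[rs == 0] <- 1
    w <- w / rs
  }
  structure(w, scheme = scheme)
}

#' Global Moran's I with a normality-null z-test
#'
#' I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2,
#' with expectation -1/(n-1) and the closed-form variance under the
#' normality null; Z = (I - E) / sd and a two-sided p-value. Used, as in the
#' source workflow, purely as a diagnostic for residual spatial structure in
#' the cohort.
#'
#' @param values Numeric vector (>= 8 finite values with coordinates).
#' @param coords Data frame with `lon`, `lat` for each value.
#' @param scheme,k,row_standardize Passed to [spatial_weights()].
#' @param weights Optional precomputed weight matrix (overrides `scheme`).
#' @return List: `I`, `expectation`, `sd`, `Z`, `p`, `n`.
#' @export
morans_i <- function(values, coords, scheme = "inverse_distance", k = 4L,
                     row_standardize = TRUE, weights = NULL) {
  ok <- is.finite(values)
  x <- values[ok]
  n <- length(x)
  if (n < 8L) cg_stop("need at least 8 cities with finite values")
  w <- if (is.null(weights))
    spatial_weights(as.data.frame(coords)[ok, , drop = FALSE], scheme, k,
                    row_standardize)
  else weights[ok, ok, drop = FALSE]
  xc <- x - mean(x)
  s0 <- sum(w)
  I <- (n / s0) * sum(w * outer(xc, xc)) / sum(xc^2)
  E <- -1 / (n - 1)
  s1 <- sum((w + t(w))^2) / 2
  s2 <- sum((rowSums(w) + colSums(w))^2)
  varI <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) - E^2
  Z <- (I - E) / sqrt(varI)
  list(I = I, expectation = E, sd = sqrt(varI), Z = Z,
       p = 2 * pnorm(-abs(Z)), n = n)
}

#' PCA with eigenvalue-one retention and varimax rotation
#'
#' Principal components of the standardized data; components with eigenvalue
#' greater than one are retained (if none clears one, the first component is
#' kept and the result flagged), then varimax-rotated for interpretability
#' when two or more are kept. Loadings are component loadings (eigenvector
#' scaled by the component standard deviation); variables with |loading| above
#' the strong-loading threshold are flagged per component.
#'
#' @param z_table Data frame or matrix of variables (complete cases are
#'   used; must have more rows than variables).
#' @param strong_loading_threshold Absolute loading flagged as strong
#'   (default 0.4).
#' @return List of class `cg_pca`: `loadings` (variables x retained
#'   components, rotated), `variance_explained`, `eigenvalues` (all),
#'   `n_retained`, `rotation`, `strong` (logical matrix), `none_above_one`.
#' @export
pca_varimax <- function(z_table, strong_loading_threshold = 0.4) {
  m <- as.matrix(as.data.frame(z_table))
  if (!is.numeric(m)) cg_stop("z_table must be numeric")
  m <- m[complete.cases(m), , drop = FALSE]
  p <- ncol(m)
  if (p < 3L) cg_stop("need at least 3 variables")
  if (nrow(m) <= p) cg_stop("fewer (complete) rows than variables")
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  keep <- which(eig > 1)
  none_above_one <- length(keep) == 0L
  if (none_above_one) keep <- 1L
  load <- pc$rotation[, keep, drop = FALSE] %*% diag(pc$sdev[keep],
                                                     length(keep))
  colnames(load) <- paste0("PC", keep)
  rotation <- "none"
  if (length(keep) >= 2L) {
    vm <- varimax(load, normalize = TRUE)
    load <- unclass(vm$loadings)
    colnames(load) <- paste0("RC", seq_along(keep))
    rotation <- "varimax"
  }
  ve <- colSums(load^2) / p
  structure(list(loadings = load, variance_explained = ve,
                 eigenvalues = eig, n_retained = length(keep),
                 rotation = rotation,
                 strong = abs(load) > strong_loading_threshold,
                 strong_loading_threshold = strong_loading_threshold,
                 none_above_one = none_above_one),
            class = "cg_pca")
}

#' @export
print.cg_pca <- function(x, ...) {
  cat(sprintf("PCA: %d component(s) retained (eigenvalue > 1), %s rotation\n",
              x$n_retained, x$rotation))
  cat("variance explained:", paste(sprintf("%.1f%%",
                                           100 * x$variance_explained),
                                   collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Bayesian linear regression with vague priors by Gibbs sampling
#'
#' Gaussian linear model with a flat prior on the coefficients and the
#' Jeffreys prior on the error variance, fit by a conjugate Gibbs sampler
#' (draws of beta | sigma^2 from the exact conditional normal and of
#' sigma^2 | beta from the conditional inverse gamma). Defaults follow the
#' reference analysis protocol: 10,000 iterations, burn-in 2,000, thinning 1.
#' A coefficient is flagged significant when its 2.5-97.5% credible interval
#' excludes zero. Convergence is screened by the split-Rhat of the retained
#' draws (warning above 1.1).
#'
#' @param y Response vector.
#' @param X Predictor matrix or data frame (complete cases required).
#' @param iterations,burn_in,thin MCMC schedule; retained draws =
#'   (iterations - burn_in) / thin, which must be >= 2.
#' @param add_intercept Prepend an intercept column (default `TRUE`).
#' @param seed Optional seed (caller's RNG stream preserved).
#' @return Object of class `cg_bayesfit`: `draws` (retained draws x
#'   coefficients), `summary` data frame (mean, sd, `ci_2.5`, `ci_97.5`,
#'   `significant`, `rhat`), `sigma` draws, and the schedule.
#' @export
bayes_regression <- function(y, X, iterations = 10000L, burn_in = 2000L,
                             thin = 1L, add_intercept = TRUE, seed = NULL) {
  X <- as.matrix(as.data.frame(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (add_intercept) X <- cbind(`(Intercept)` = 1, X)
  keep <- complete.cases(X) & is.finite(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) cg_stop("need more observations than coefficients")
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    cg_stop("predictor matrix is rank deficient; collinear column(s): ",
            paste(dropped, collapse = ", "))
  }
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in < 0 || burn_in >= iterations || thin < 1)
    cg_stop("invalid MCMC schedule")
  retained <- (iterations - burn_in) %/% thin
  if (retained < 2L)
    cg_stop("schedule retains ", retained,
            " draw(s); need at least 2 (reduce burn_in or thin)")

  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  XtX_inv <- chol2inv(chol(XtX))
  beta_hat <- drop(XtX_inv %*% Xty)
  L <- chol(XtX_inv)  # upper triangular, t(L) %*% L = XtX_inv

  draws <- with_seed(seed, {
    out <- matrix(NA_real_, retained, p)
    sig_out <- numeric(retained)
    resid0 <- y - drop(X %*% beta_hat)
    sigma2 <- sum(resid0^2) / (n - p)
    r <- 0L
    for (it in seq_len(iterations)) {
      beta <- beta_hat + sqrt(sigma2) * drop(crossprod(L, rnorm(p)))
      rss <- sum((y - drop(X %*% beta))^2)
      sigma2 <- rss / (2 * rgamma(1, shape = n / 2, rate = 1))  # 1/Gamma
      if (it > burn_in && (it - burn_in) %% thin == 0L) {
        r <- r + 1L
        out[r, ] <- beta
        sig_out[r] <- sigma2
      }
    }
    list(beta = out, sigma2 = sig_out)
  })
  colnames(draws$beta) <- colnames(X)

  qs <- apply(draws$beta, 2, quantile, probs = c(0.025, 0.975))
  rhat <- apply(draws$beta, 2, split_rhat)
  summary <- data.frame(
    coefficient = colnames(X),
    mean = colMeans(draws$beta),
    sd = apply(draws$beta, 2, sd),
    ci_2.5 = qs[1, ], ci_97.5 = qs[2, ],
    significant = qs[1, ] > 0 | qs[2, ] < 0,
    rhat = rhat, row.names = NULL, stringsAsFactors = FALSE)
  if (any(is.finite(rhat) & rhat > 1.1))
    cg_warn("split-Rhat above 1.1 for: ",
            paste(summary$coefficient[is.finite(rhat) & rhat > 1.1],
                  collapse = ", "),
            class = "citygreen_nonconvergence")
  structure(list(draws = draws$beta, sigma2 = draws$sigma2,
                 summary = summary,
                 mcmc = list(iterations = iterations, burn_in = burn_in,
                             thin = thin, retained = retained, seed = seed),
                 n = n),
            class = "cg_bayesfit")
}

split_rhat <- function(x) {
  m <- length(x) %/% 2L
  if (m < 2L) return(NA_real_)
  chains <- cbind(x[seq_len(m)], x[m + seq_len(m)])
  W <- mean(apply(chains, 2, stats::var))
  B <- m * stats::var(colMeans(chains))
  if (W == 0) return(NA_real_)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' @export
print.cg_bayesfit <- function(x, ...) {
  cat(sprintf("Bayesian linear model (%d draws retained of %d, burn-in %d)\n",
              x$mcmc$retained, x$mcmc$iterations, x$mcmc$burn_in))
  s <- x$summary
  s[, sapply(s, is.numeric)] <- round(s[, sapply(s, is.numeric)], 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits the one-way analysis of variance, reports r^2, F and p, runs Tukey's
#' HSD on all pairs at the given alpha, and assigns compact letters by
#' enumerating the maximal cliques of the not-significantly-different graph
#' in order of decreasing group mean — so groups sharing a letter are never
#' significantly different, and every non-significant pair shares one.
#' Groups with fewer than 2 observations are dropped with a warning.
#'
#' @param values Numeric response.
#' @param groups Factor (or coercible) of group labels.
#' @param alpha Significance level for the HSD tests (default 0.05).
#' @return Object of class `cg_anova`: `r2`, `F`, `p`, `groups` data frame
#'   (group, n, mean, min, max, letters), `tukey` (pairwise table).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  ok <- is.finite(values) & !is.na(g)
  values <- values[ok]; g <- droplevels(g[ok])
  sizes <- table(g)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    cg_warn("dropping group(s) with n < 2: ", paste(small, collapse = ", "),
            class = "citygreen_small_group")
    keep <- !(g %in% small)
    values <- values[keep]; g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2L) cg_stop("need at least 2 groups with n >= 2")

  fit <- aov(values ~ g)
  an <- stats::anova(fit)
  ss <- an[["Sum Sq"]]
  r2 <- ss[1] / sum(ss)
  Fv <- an[["F value"]][1]
  pv <- an[["Pr(>F)"]][1]

  hsd <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  # rows of TukeyHSD follow combn(levels, 2) as "second-first"; rebuild the
  # pairs positionally (labels may themselves contain '-')
  cmb <- utils::combn(levels(g), 2)
  pairs <- cbind(cmb[2, ], cmb[1, ])
  stopifnot(nrow(hsd) == ncol(cmb))
  tukey <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                      diff = hsd[, "diff"], p_adj = hsd[, "p adj"],
                      row.names = NULL, stringsAsFactors = FALSE)

  letters_df <- compact_letters(levels(g),
                                tapply(values, g, mean),
                                tukey, alpha)
  stats_df <- data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(values, g, mean)),
    min = as.numeric(tapply(values, g, min)),
    max = as.numeric(tapply(values, g, max)),
    letters = unname(letters_df[levels(g)]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(r2 = r2, F = Fv, p = pv, groups = stats_df, tukey = tukey,
                 alpha = alpha),
            class = "cg_anova")
}

# compact letter display: maximal cliques of the non-significance graph,
# lettered in order of the highest mean they contain
compact_letters <- function(groups, means, tukey, alpha) {
  k <- length(groups)
  if (k > 20L) cg_stop("compact letter display supports at most 20 groups")
  ns <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(tukey))) {
    if (tukey$p_adj[i] < alpha) {
      a <- tukey$group1[i]; b <- tukey$group2[i]
      ns[a, b] <- ns[b, a] <- FALSE
    }
  }
  # maximal cliques by subset enumeration (k is small)
  cliques <- list()
  for (code in seq_len(2^k - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    sub <- ns[members, members, drop = FALSE]
    if (all(sub)) cliques[[length(cliques) + 1]] <- members
  }
  is_maximal <- vapply(cliques, function(ci) {
    !any(vapply(cliques, function(cj)
      length(cj) > length(ci) && all(ci %in% cj), TRUE))
  }, TRUE)
  cliques <- cliques[is_maximal]
  best_mean <- vapply(cliques, function(ci) max(means[ci]), 0)
  cliques <- cliques[order(-best_mean)]
  out <- setNames(rep("", k), groups)
  for (i in seq_along(cliques))
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[i])
  out
}

#' @export
print.cg_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: r2 = %.3f, F = %.2f, p = %.4g\n",
              x$r2, x$F, x$p))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Pairwise Spearman synergy/tradeoff matrices, overall and by category
#'
#' Spearman rank correlations (tie-corrected, two-sided p) between all pairs
#' of services, for all cities together and within each level of the
#' supplied category columns. Strata smaller than `min_n` (or with a
#' constant service) are reported as `NA` with a warning. The default star
#' scheme reproduces the reference report's legend verbatim
#' (* p<0.01, ** p<0.05, *** p<0.001); `star_scheme = "conventional"` uses
#' the usual ordering (* p<0.05, ** p<0.01, *** p<0.001). No multiple-testing
#' correction is applied across strata, matching the reference analysis.
#'
#' @param service_table Data frame of per-city services.
#' @param category_table Optional data frame of factor columns (same row
#'   order) defining the strata.
#' @param service_cols Columns of `service_table` to correlate.
#' @param min_n Minimum stratum size (default 5).
#' @param star_scheme `"report"` (default) or `"conventional"`.
#' @return Data frame of class `cg_synergy`: `stratum_type`, `stratum`,
#'   `pair`, `rho`, `p`, `n`, `stars`.
#' @export
spearman_synergies <- function(service_table, category_table = NULL,
                               service_cols = c("recreation_m2_per_capita",
                                                "carbon_t_per_ha",
                                                "habitat_potential_pct"),
                               min_n = 5L,
                               star_scheme = c("report", "conventional")) {
  star_scheme <- match.arg(star_scheme)
  missing_cols <- setdiff(service_cols, names(service_table))
  if (length(missing_cols))
    cg_stop("missing service columns: ", paste(missing_cols, collapse = ", "))
  strata <- list(list(type = "all", name = "all",
                      rows = seq_len(nrow(service_table))))
  if (!is.null(category_table)) {
    for (cl in names(category_table)) {
      f <- factor(category_table[[cl]])
      for (lv in levels(f)) {
        strata[[length(strata) + 1]] <-
          list(type = cl, name = lv, rows = which(f == lv))
      }
    }
  }
  pairs <- utils::combn(service_cols, 2, simplify = FALSE)
  rows <- list()
  warn_small <- character()
  for (st in strata) {
    for (pr in pairs) {
      x <- service_table[[pr[1]]][st$rows]
      y <- service_table[[pr[2]]][st$rows]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      rho <- p <- NA_real_
      if (n < min_n) {
        warn_small <- c(warn_small, paste0(st$type, ":", st$name))
      } else if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        cg_warn("constant service in stratum ", st$type, ":", st$name,
                class = "citygreen_constant_stratum")
      } else {
        ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                        exact = FALSE))
        rho <- unname(ct$estimate)
        p <- ct$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        stratum_type = st$type, stratum = st$name,
        pair = paste(pr, collapse = " vs "),
        rho = rho, p = p, n = n,
        stars = star_label(p, star_scheme),
        stringsAsFactors = FALSE)
    }
  }
  if (length(warn_small))
    cg_warn("strata below the minimum size reported as NA: ",
            paste(unique(warn_small), collapse = ", "),
            class = "citygreen_small_stratum")
  out <- do.call(rbind, rows)
  attr(out, "star_scheme") <- star_scheme
  class(out) <- c("cg_synergy", class(out))
  out
}

star_label <- function(p, scheme) {
  if (is.na(p)) return("")
  if (scheme == "report") {
    # verbatim report legend: * p<0.01, ** p<0.05, *** p<0.001
    if (p < 0.001) "***" else if (p < 0.01) "*" else if (p < 0.05) "**" else ""
  } else {
    if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  }
}
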