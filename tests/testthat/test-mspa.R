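# Morphological spatial pattern analysis: segmentation, patch table,
# habitat potential.

CODES <- mspa_classes()

test_that("all-background raster maps entirely to background", {
  m <- mspa_segment(rg(matrix(FALSE, 12, 12)))
  expect_true(all(m$labels == CODES[["background"]]))
})

test_that("a 5x5 block at edge width 2 has no core and becomes an islet", {
  v <- block_mask(15, 15, 6:10, 6:10)
  m <- mspa_segment(rg(v))
  expect_false(any(m$labels == CODES[["core"]]))
  expect_identical(m$labels == CODES[["islet"]], v)
  expect_identical(m$labels, oracle_mspa(v))
})

test_that("a 9x9 block has a central core surrounded by edge", {
  v <- block_mask(21, 21, 7:15, 7:15)
  m <- mspa_segment(rg(v))
  o <- oracle_mspa(v)
  expect_identical(m$labels, o)
  core <- m$labels == CODES[["core"]]
  expect_identical(core, block_mask(21, 21, 10:12, 10:12))  # 3x3 center
  expect_true(all(m$labels[v & !core] == CODES[["edge"]]))
  expect_false(any(m$labels == CODES[["islet"]]))
})

test_that("a perforated block shows perforation on the hole side only", {
  v <- block_mask(27, 27, 5:23, 5:23)
  v[13:15, 13:15] <- FALSE  # interior hole
  m <- mspa_segment(rg(v))
  expect_identical(m$labels, oracle_mspa(v))
  perf <- which(m$labels == CODES[["perforation"]], arr.ind = TRUE)
  expect_gt(nrow(perf), 0)
  # perforation pixels hug the hole, not the outer edge
  expect_true(all(abs(perf[, 1] - 14) <= 5 & abs(perf[, 2] - 14) <= 5))
  expect_true(any(m$labels == CODES[["edge"]]))
})

test_that("a thin corridor between two cores is a bridge", {
  v <- matrix(FALSE, 21, 45)
  v[6:14, 3:11] <- TRUE    # block with core
  v[6:14, 35:43] <- TRUE   # second block with core
  v[10, 12:34] <- TRUE     # 1-px corridor
  m <- mspa_segment(rg(v))
  expect_identical(m$labels, oracle_mspa(v))
  expect_true(any(m$labels == CODES[["bridge"]]))
  expect_false(any(m$labels == CODES[["loop"]]))
})

test_that("a thin arc re-entering the same core is a loop, a stub a branch", {
  v <- matrix(FALSE, 30, 30)
  v[10:18, 4:12] <- TRUE   # core block
  v[5:9, 8] <- TRUE        # arc leaving the top of the block ...
  v[5, 8:24] <- TRUE       # ... across ...
  v[5:14, 24] <- TRUE      # ... down ...
  v[14, 13:24] <- TRUE     # ... and back into the block's right edge
  loopm <- mspa_segment(rg(v))
  expect_identical(loopm$labels, oracle_mspa(v))
  expect_true(any(loopm$labels == CODES[["loop"]]))

  v2 <- matrix(FALSE, 30, 30)
  v2[10:18, 4:12] <- TRUE
  v2[14, 13:26] <- TRUE    # dead-end stub
  stubm <- mspa_segment(rg(v2))
  expect_identical(stubm$labels, oracle_mspa(v2))
  expect_true(any(stubm$labels == CODES[["branch"]]))
  expect_false(any(stubm$labels %in% CODES[c("loop", "bridge")]))
})

test_that("classes exactly partition vegetation on random grids", {
  for (seed in 1:8) {
    v <- random_mask(40, 40, 0.3 + 0.05 * seed, seed)
    m <- mspa_segment(rg(v))
    expect_identical(m$labels > 0L, v)
    counts <- table(factor(m$labels, levels = CODES))
    expect_identical(sum(counts[-1]), sum(v))
  }
})

test_that("euclidean and chebyshev agree with the oracle on random grids", {
  for (seed in c(101, 102, 103)) {
    v <- random_mask(30, 30, 0.55, seed)
    for (metric in c("euclidean", "chebyshev")) {
      m <- mspa_segment(rg(v), mspa_params(distance_metric = metric))
      o <- oracle_mspa(v, metric = metric)
      expect_identical(m$labels, o)
    }
  }
})

test_that("core area is monotone non-increasing in edge width", {
  for (seed in c(21, 22)) {
    v <- random_mask(50, 50, 0.75, seed)
    cores <- vapply(1:4, function(w)
      sum(mspa_segment(rg(v), mspa_params(edge_width_px = w))$labels ==
            CODES[["core"]]), 0L)
    expect_true(all(diff(cores) <= 0L))
  }
})

test_that("perforation occurs only in patches containing core", {
  seen_perforation <- FALSE
  for (seed in c(31, 32, 33)) {
    v <- random_mask(45, 45, 0.7, seed)
    m <- mspa_segment(rg(v))
    lab <- citygreen:::.cg_label(v, 8L)
    perf_patches <- unique(lab[m$labels == CODES[["perforation"]]])
    core_patches <- unique(lab[m$labels == CODES[["core"]]])
    expect_true(all(perf_patches %in% core_patches))
    if (length(perf_patches)) seen_perforation <- TRUE
  }
  # a perforated block guarantees the property is exercised at least once
  v <- block_mask(27, 27, 5:23, 5:23); v[13:15, 13:15] <- FALSE
  m <- mspa_segment(rg(v))
  expect_true(any(m$labels == CODES[["perforation"]]))
})

test_that("connectivity parameters are validated", {
  expect_error(mspa_params(fg_connectivity = 4, bg_connectivity = 4),
               "Jordan")
  expect_error(mspa_params(edge_width_px = 0), "positive integer")
  expect_error(mspa_segment(rg(matrix(0.5, 4, 4))), "binary")
})

test_that("patch table reports areas in hectares", {
  v <- block_mask(20, 20, 3:6, 3:6)  # 16 pixels of 900 m2 = 1.44 ha
  m <- mspa_segment(rg(v))
  pt <- mspa_patch_table(rg(v), m)
  expect_equal(nrow(pt), 1L)
  expect_equal(pt$area_ha, 1.44)

  v2 <- v | block_mask(20, 20, 12:15, 12:17)
  pt2 <- mspa_patch_table(rg(v2), mspa_segment(rg(v2)))
  expect_equal(nrow(pt2), 2L)
  expect_equal(sum(pt2$area_ha), sum(v2) * 900 / 1e4)

  empty <- mspa_patch_table(rg(matrix(FALSE, 5, 5)),
                            mspa_segment(rg(matrix(FALSE, 5, 5))))
  expect_equal(nrow(empty), 0L)
})

test_that("habitat potential follows the brute-force core count", {
  v <- block_mask(21, 21, 7:15, 7:15)  # 81 px = 7.29 ha, qualifies
  k <- sum(oracle_mspa(v) == CODES[["core"]])
  pt <- mspa_patch_table(rg(v), mspa_segment(rg(v)))
  hp <- habitat_potential(pt)
  expect_equal(as.numeric(hp), k * 0.09 / 7.29)
})

test_that("habitat potential is undefined without qualifying patches", {
  v <- block_mask(20, 20, 3:5, 3:5)  # 9 px = 0.81 ha < 1.44
  pt <- mspa_patch_table(rg(v), mspa_segment(rg(v)))
  expect_warning(hp <- habitat_potential(pt),
                 class = "citygreen_undefined_habitat")
  expect_true(is.na(hp))
})

test_that("habitat potential approaches 1 for ever-larger solid patches", {
  hps <- vapply(c(15, 31, 61), function(n) {
    v <- matrix(TRUE, n, n)
    v <- rbind(FALSE, cbind(FALSE, v, FALSE), FALSE)
    as.numeric(habitat_potential(mspa_patch_table(rg(v),
                                                  mspa_segment(rg(v)))))
  }, 0)
  expect_true(all(diff(hps) > 0))
  expect_gt(hps[3], 0.75)
})

test_that("alternative habitat denominators are available", {
  v <- block_mask(21, 21, 7:15, 7:15)
  pt <- mspa_patch_table(rg(v), mspa_segment(rg(v)))
  hp_urban <- habitat_potential(pt, denominator = "urban_area",
                                urban_area_ha = 21^2 * 0.09)
  hp_default <- habitat_potential(pt)
  expect_lt(as.numeric(hp_urban), as.numeric(hp_default))
  expect_error(habitat_potential(pt, denominator = "urban_area"),
               "urban_area_ha")
})
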