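test_that("yield reference thresholds at the percentile of positive yields", {
  geom <- grid_geometry(0, 5, 0, 5, 0.5)
  y <- matrix(c(1:100), 10, 10)
  ref <- reference_from_yield(geo_grid(y, geom))
  # sort-and-interpolate oracle: h = (n-1)p + 1
  pos <- sort(as.vector(y))
  h <- (length(pos) - 1) * 0.25 + 1
  cutoff <- pos[floor(h)] + (h - floor(h)) * (pos[floor(h) + 1] - pos[floor(h)])
  expect_equal(ref$cutoff, cutoff)
  expect_equal(ref$cutoff, 25.75)
  expect_equal(ref$labels, y >= 25.75)
  # zeros are unsuitable but in the mask; NAs are outside it
  y2 <- y; y2[1, 1] <- 0; y2[2, 2] <- NA
  ref2 <- reference_from_yield(geo_grid(y2, geom))
  expect_false(ref2$labels[1, 1])
  expect_true(ref2$mask[1, 1])
  expect_false(ref2$mask[2, 2])
  # all equal positive -> all suitable; all zero -> error
  ref3 <- reference_from_yield(geo_grid(matrix(5, 10, 10), geom))
  expect_true(all(ref3$labels))
  expect_error(reference_from_yield(geo_grid(matrix(0, 10, 10), geom)),
               "positive")
  expect_error(reference_from_yield(geo_grid(matrix(-1, 10, 10), geom)),
               "non-negative")
})

test_that("percentile labels match the sort oracle on random grids", {
  geom <- grid_geometry(0, 10, 0, 10, 0.5)
  for (seed in 1:5) {
    y <- local_seed(seed, matrix(rexp(400) * rbinom(400, 1, 0.8), 20, 20))
    ref <- reference_from_yield(geo_grid(y, geom))
    pos <- y[y > 0]
    cutoff <- as.numeric(stats::quantile(pos, 0.25))
    expect_equal(ref$labels, y >= cutoff)
  }
})

test_that("confusion rates come from the stated confusion matrix", {
  sc <- c(0.2, 0.4, 0.6, 0.8); lb <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(confusion_rates(sc, lb, 0.5), c(se = 1, sp = 1))
  expect_equal(confusion_rates(sc, lb, 0)[["se"]], 1)
  expect_equal(confusion_rates(sc, lb, 0)[["sp"]], 0)
  expect_equal(confusion_rates(sc, lb, 0.9), c(se = 0, sp = 1))
  expect_equal(confusion_rates(sc, lb, 0.7), c(se = 0.5, sp = 1))
  expect_error(confusion_rates(sc, rep(TRUE, 4), 0.5), "both classes")
})

test_that("equalize_se_sp equals the exhaustive scan, with stated tie-breaks", {
  # separable classes: gap 0 at Se = Sp = 1
  sep <- equalize_se_sp(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sep$gap, 0)
  expect_equal(sep$se, 1)
  expect_equal(sep$sp, 1)
  # random sets against the brute-force oracle
  for (seed in 1:100) {
    n <- 20 + seed %% 30
    sc <- local_seed(seed, round(runif(n), 2))
    lb <- local_seed(seed + 1000, runif(n) < 0.4)
    if (!any(lb) || all(lb)) next
    got <- equalize_se_sp(sc, lb)
    want <- oracle_equalize(sc, lb)
    expect_equal(got$gap, want$gap)
    expect_equal(got$se + got$sp, want$se + want$sp)
    expect_equal(got$threshold, want$threshold)
  }
  # labels independent of scores: threshold near the score median
  big_sc <- local_seed(11, runif(4000))
  big_lb <- local_seed(12, runif(4000) < 0.5)
  th <- equalize_se_sp(big_sc, big_lb)
  expect_lt(abs(th$threshold - stats::median(big_sc)), 0.05)
  expect_error(equalize_se_sp(c(0.1, 0.9), c(TRUE, TRUE)), "both classes")
})

test_that("binarize is boundary-inclusive and propagates missing", {
  geom <- grid_geometry(0, 1.5, 0, 0.5, 0.5)
  m <- suitability_map(matrix(c(0.2, 0.5, NA), 1, 3), geom, "maize", "curr")
  b <- binarize(m, 0.5)
  expect_identical(as.vector(b$values), c(FALSE, TRUE, NA))
  expect_true(all(binarize(m, 0)$values[!is.na(m$values)]))
  b1 <- binarize(m, 1)
  expect_identical(as.vector(b1$values), c(FALSE, FALSE, NA))
  expect_error(binarize(m, 1.2))
})

test_that("match_score counts agreements on the evaluation mask", {
  geom <- grid_geometry(0, 1, 0, 1, 0.5)
  ref <- reference_from_yield(geo_grid(matrix(c(1, 2, 3, 4), 2, 2), geom))
  agree <- geo_grid(ref$labels, geom)
  expect_equal(match_score(agree, ref), 1)
  expect_equal(match_score(geo_grid(!ref$labels, geom), ref), 0)
  three <- ref$labels; three[1, 1] <- !three[1, 1]
  expect_equal(match_score(geo_grid(three, geom), ref), 0.75)
})

test_that("match at the equalized threshold is invariant under monotone score transforms", {
  wrld <- random_world(21, nr = 8, nc = 8)
  p <- test_params()
  map <- map_suitability(wrld$stack, wrld$ph, p)
  ref <- reference_from_yield(make_yield_grid(
    suitability_map(map$values, map$geom), 0.1, seed = 4))
  base_ev <- function(m) {
    th <- equalize_se_sp(as.vector(m$values), as.vector(ref$labels))
    match_score(binarize(m, th$threshold), ref)
  }
  m0 <- base_ev(map)
  sq <- geo_grid(map$values^2, map$geom)   # strictly monotone on [0,1]
  expect_equal(base_ev(sq), m0)
})

test_that("rainfall calibration converges near the true minimum on the recovery world", {
  p_true <- recovery_crop()
  for (seed in 1:3) {
    w <- make_world(recovery_world_spec(seed))
    truth <- make_truth(w, p_true)
    ref <- reference_from_yield(make_yield_grid(truth, 0.1,
                                                seed = derive_seed(seed, 9)))
    p0 <- degrade_params(p_true, rain = 30, niche = 0)
    res <- calibrate_rainfall(p0, w$stack, w$ph, ref)
    expect_equal(res$status, "converged")
    expect_lte(nrow(res$trace) - 1, 3)           # recovery within 3 steps
    expect_lte(abs(res$params$rmin - p_true$rmin), 10)
    expect_gte(res$match, 0.7)
    # never worse than the starting state
    expect_gte(res$match, res$trace$match[1])
  }
})

test_that("rainfall calibration stops immediately when already matching, and retains best otherwise", {
  w <- make_world(recovery_world_spec(4))
  p_true <- recovery_crop()
  truth <- make_truth(w, p_true)
  ref <- reference_from_yield(make_yield_grid(truth, 0.1, seed = 2))
  res <- calibrate_rainfall(p_true, w$stack, w$ph, ref)
  expect_equal(res$status, "converged")
  expect_equal(nrow(res$trace), 1)
  expect_equal(res$params$rmin, p_true$rmin)
  # unreachable target: floor everything, retain the best-scoring state
  res2 <- calibrate_rainfall(p_true, w$stack, w$ph, ref, target = 0.999,
                             step = 400)
  expect_equal(res2$status, "retained_best")
  expect_equal(res2$match, max(res2$trace$match))
  expect_gte(res2$match, res2$trace$match[1])
})

test_that("temperature calibration recovers a niche shift within one step", {
  p_true <- tent_crop()
  for (seed in 1:3) {
    w <- make_world(tent_world_spec(seed + 10))
    truth <- make_truth(w, p_true)
    ref <- reference_from_yield(make_yield_grid(truth, 0.1,
                                                seed = derive_seed(seed, 5)))
    p0 <- degrade_params(p_true, rain = 0, niche = -2)
    res <- calibrate_temperature(p0, w$stack, w$ph, ref)
    expect_equal(res$status, "converged")
    expect_lte(abs(res$niche_offset - 2), 1)
    expect_lte(abs(res$ktmp_offset), 1)
    expect_gte(res$match, 0.7)
  }
})

test_that("temperature search is identity-first and exhaustive when unreachable", {
  w <- make_world(recovery_world_spec(8))
  p_true <- recovery_crop()
  truth <- make_truth(w, p_true)
  ref <- reference_from_yield(make_yield_grid(truth, 0.1, seed = 3))
  res <- calibrate_temperature(p_true, w$stack, w$ph, ref)
  expect_equal(res$status, "converged")
  expect_equal(nrow(res$trace), 1)   # (0, 0) evaluated first and sufficient
  expect_equal(res$niche_offset, 0)
  res2 <- calibrate_temperature(p_true, w$stack, w$ph, ref, target = 1.01)
  expect_equal(res2$status, "retained_best")
  expect_equal(nrow(res2$trace), 121)  # 11 x 11 grid exhausted
  expect_gte(res2$match, res2$trace$match[1])
})
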