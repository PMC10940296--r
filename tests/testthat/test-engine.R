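test_that("trapezoid matches its piecewise definition, including degenerates", {
  # plateau, bounds, midpoints
  expect_equal(trapezoid_suitability(15, 10, 15, 25, 30), 1)
  expect_equal(trapezoid_suitability(10, 10, 15, 25, 30), 0)
  expect_equal(trapezoid_suitability(12.5, 10, 15, 25, 30), 0.5)
  expect_equal(trapezoid_suitability(27.5, 10, 15, 25, 30), 0.5)
  # vectorized, NA propagates
  expect_equal(trapezoid_suitability(c(9, NA, 26), 10, 15, 25, 30),
               c(0, NA, 0.8))
  # degenerate bounds act as steps
  expect_equal(trapezoid_suitability(c(9.99, 10, 10.01), 10, 10, 25, 30),
               c(0, 1, 1))
  expect_equal(trapezoid_suitability(c(24.9, 25, 25.1), 10, 15, 25, 25),
               c(1, 1, 0))
  expect_error(trapezoid_suitability(5, 10, 9, 25, 30), "amin <= omin")
  # random inputs agree with the scalar oracle
  local_seed(42, {
    for (k in 1:50) {
      b <- sort(runif(4, 0, 40))
      x <- runif(1, -5, 45)
      expect_equal(trapezoid_suitability(x, b[1], b[2], b[3], b[4]),
                   oracle_trap(x, b[1], b[2], b[3], b[4]))
    }
  })
})

test_that("duration and growing windows follow the stated rules", {
  expect_identical(duration_months(test_params(gmin = 90, gmax = 120)), 4L)
  expect_identical(duration_months(test_params(gmin = 360, gmax = 360)), 12L)
  expect_identical(duration_months(test_params(gmin = 30, gmax = 30)), 1L)
  expect_identical(duration_months(test_params(gmin = 120, gmax = 180)), 5L)
  expect_identical(growing_window(11, 4), c(11L, 12L, 1L, 2L))
  expect_identical(growing_window(1, 12), 1:12)
  expect_identical(growing_window(6, 1), 6L)
  expect_error(growing_window(6, 13), "duration")
  expect_error(growing_window(6, 0), "duration")
})

test_that("seasonal temperature score is the window minimum with kill test", {
  p <- test_params()
  cfg <- engine_config()
  opt <- (p$topmin + p$topmax) / 2
  expect_equal(temp_suitability_season(rep(opt, 12), p, 1:4, cfg), 1)
  # one frosty month zeroes the window via tminm
  tm <- rep(opt, 12)
  tn <- rep(opt - 5, 12); tn[2] <- p$ktmp + cfg$frost_buffer - 0.1
  expect_equal(temp_suitability_season(tm, p, 1:4, cfg, tminm = tn), 0)
  # monthly scores {1.0, 0.6, 0.8} -> window minimum 0.6
  x_for <- function(s) p$tmin + s * (p$topmin - p$tmin)  # lower-ramp inverse
  tm2 <- rep(opt, 12); tm2[1] <- x_for(1); tm2[2] <- x_for(0.6); tm2[3] <- x_for(0.8)
  expect_equal(temp_suitability_season(tm2, p, 1:3, cfg), 0.6)
  expect_true(is.na(temp_suitability_season(c(NA, rep(opt, 11)), p, 1:2, cfg)))
})

test_that("seasonal rainfall score uses the window total", {
  p <- test_params()
  pr <- rep(p$ropmin / 4, 12)
  expect_equal(rain_suitability_season(pr, p, 1:4), 1)
  expect_equal(rain_suitability_season(rep(0, 12), p, 1:4), 0)
  pr2 <- rep((p$rmin + p$ropmin) / 8, 12)
  expect_equal(rain_suitability_season(pr2, p, 1:4), 0.5)
})

test_that("cell suitability maximizes over windows and combines with pH", {
  p <- test_params(gmin = 60, gmax = 60)  # 2-month window
  cfg <- engine_config()
  opt_t <- (p$topmin + p$topmax) / 2
  # exactly one viable window: months 5-6 carry all rain and good temps
  tm <- rep(p$tmax + 5, 12); tm[5:6] <- opt_t
  pr <- rep(0, 12); pr[5] <- p$ropmin / 2; pr[6] <- p$ropmin / 2
  ph_opt <- (p$phopmin + p$phopmax) / 2
  expect_equal(cell_suitability(tm, pr, ph_opt, p, cfg), 1)
  # temp 0.8 x rain 0.5 x ph 1 under product rule
  tm[5:6] <- p$tmin + 0.8 * (p$topmin - p$tmin)
  pr[5:6] <- (p$rmin + p$ropmin) / 4
  expect_equal(cell_suitability(tm, pr, ph_opt, p, cfg), 0.4)
  # min rule instead
  expect_equal(cell_suitability(tm, pr, ph_opt, p,
                                engine_config("min", "min")), 0.5)
  # all months below kill threshold -> 0
  expect_equal(cell_suitability(rep(p$ktmp + cfg$frost_buffer - 1, 12),
                                rep(p$ropmin, 12), ph_opt, p, cfg), 0)
})

test_that("grid engine equals the scalar oracle on random worlds", {
  p <- test_params()
  for (seed in 1:20) {
    wrld <- random_world(seed, with_tminm = seed %% 2 == 0)
    cfg <- engine_config(combine_rule = if (seed %% 3) "product" else "min")
    got <- map_suitability(wrld$stack, wrld$ph, p, cfg)
    expect_equal(got$values, oracle_map(wrld$stack, wrld$ph, p, cfg),
                 tolerance = 1e-12)
  }
})

test_that("suitability maps are invariant under cyclic month rotation", {
  p <- test_params()
  wrld <- random_world(99)
  base <- map_suitability(wrld$stack, wrld$ph, p)$values
  for (k in c(1, 5, 11)) {
    rot <- c((k + 1):12, 1:k)
    st <- climate_stack(wrld$stack$tmean[, , rot], wrld$stack$prec[, , rot],
                        tminm = wrld$stack$tminm[, , rot],
                        geom = wrld$stack$geom)
    expect_equal(map_suitability(st, wrld$ph, p)$values, base)
  }
})

test_that("widening the niche never decreases suitability", {
  p <- test_params()
  wrld <- random_world(7)
  base <- map_suitability(wrld$stack, wrld$ph, p)$values
  wider <- list(
    test_params(rmin = p$rmin - 100, ropmin = p$ropmin - 100),
    test_params(tmin = p$tmin - 3),
    test_params(tmax = p$tmax + 3, topmax = p$topmax + 3),
    test_params(phmin = p$phmin - 1, phopmin = p$phopmin - 1))
  for (w in wider) {
    v <- map_suitability(wrld$stack, wrld$ph, w)$values
    expect_true(all(v >= base - 1e-12, na.rm = TRUE))
  }
})

test_that("product combination is dominated by min combination", {
  p <- test_params()
  wrld <- random_world(13)
  prod <- map_suitability(wrld$stack, wrld$ph, p,
                          engine_config("product", "product"))$values
  mn <- map_suitability(wrld$stack, wrld$ph, p,
                        engine_config("min", "min"))$values
  expect_true(all(prod <= mn + 1e-12, na.rm = TRUE))
  expect_true(all(prod >= 0 & prod <= 1, na.rm = TRUE))
  expect_true(all(mn >= 0 & mn <= 1, na.rm = TRUE))
})

test_that("masked and missing cells propagate as missing", {
  p <- test_params()
  geom <- grid_geometry(0, 1, 0, 1, 0.5)
  opt_t <- (p$topmin + p$topmax) / 2
  tmean <- array(opt_t, c(2, 2, 12))
  prec <- array(p$ropmin / 4, c(2, 2, 12))
  mask <- matrix(TRUE, 2, 2); mask[2, 1] <- FALSE
  st <- climate_stack(tmean, prec, land_mask = mask, geom = geom)
  ph <- geo_grid(matrix((p$phopmin + p$phopmax) / 2, 2, 2), geom)
  out <- map_suitability(st, ph, p)
  expect_true(is.na(out$values[2, 1]))
  expect_equal(out$values[1, 1], 1)
  # missing pH stays missing rather than unconstrained
  ph$values[1, 2] <- NA
  out2 <- map_suitability(st, ph, p)
  expect_true(is.na(out2$values[1, 2]))
  # geometry mismatch errors
  ph_bad <- geo_grid(matrix(7, 2, 2), grid_geometry(0, 1, 1, 2, 0.5))
  expect_error(map_suitability(st, ph_bad, p), "geometry")
})
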