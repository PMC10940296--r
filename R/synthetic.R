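# Seeded synthetic worlds with the statistical structure the pipeline
# assumes: latitude-structured seasonal temperature, hemisphere-phased wet
# seasons with an equator-to-edge wetness taper, a smooth correlated soil-pH
# field, a rectangular country mosaic, occurrence points enriched toward
# suitable cells, harvested-area tables proportional to suitable area, and
# a yield surface proportional to suitability. Everything is reproducible
# from one seed; no stage touches global RNG state.

#' Specification of a synthetic world
#'
#' Defaults describe an Africa-like domain: 40degS-40degN x 20degW-55degE
#' at 0.5deg, equatorial annual-mean temperature 26 degC falling 0.3 degC
#' per degree of latitude, a 3 degC-amplitude seasonal cycle peaking in July north of
#' the equator and January south of it, an 8-month wet season peaking at
#' 250 mm/month at the equator and tapering toward the domain edge, and a
#' smooth soil-pH field spanning 4.5-8.5.
#'
#' @param xmin,xmax,ymin,ymax Domain extent, degrees.
#' @param res Resolution, degrees.
#' @param seed Integer master seed.
#' @param eq_tmean Equatorial annual-mean temperature, degC.
#' @param lapse Cooling per degree of absolute latitude, degC/deg.
#' @param amplitude Seasonal half-range of monthly mean temperature, degC.
#' @param t_noise_sd Additive temperature noise sd, degC.
#' @param diurnal_offset `tminm = tmean - diurnal_offset`, degC.
#' @param wet_peak Wet-season peak precipitation at the equator, mm/month.
#' @param wet_months Wet-season length, months.
#' @param dry_floor Dry-season precipitation floor, mm/month.
#' @param wet_taper Fractional reduction of the wet-season peak at the
#'   latitude edge of the domain (equator wettest).
#' @param p_noise_sd Multiplicative (lognormal) precipitation noise sd.
#' @param ph_range Soil-pH field range.
#' @param ph_corr_length Spatial correlation length of the pH field,
#'   degrees.
#' @param n_countries Number of rectangular regions in the mosaic.
#' @return A `world_spec` list.
#' @export
world_spec <- function(xmin = -20, xmax = 55, ymin = -40, ymax = 40,
                       res = 0.5, seed = 1L,
                       eq_tmean = 26, lapse = 0.3, amplitude = 3,
                       t_noise_sd = 0.5, diurnal_offset = 6,
                       wet_peak = 250, wet_months = 8, dry_floor = 10,
                       wet_taper = 0.85, p_noise_sd = 0.1,
                       ph_range = c(4.5, 8.5), ph_corr_length = 10,
                       n_countries = 12L) {
  spec <- as.list(environment())
  stopifnot(t_noise_sd >= 0, p_noise_sd >= 0, wet_taper >= 0, wet_taper <= 1)
  grid_geometry(xmin, xmax, ymin, ymax, res)  # validates divisibility
  structure(spec, class = "world_spec")
}

# smooth correlated field: coarse white noise bilinearly upsampled
smooth_field <- function(geom, corr_length, seed) {
  res_c <- corr_length
  pad <- res_c
  cg <- grid_geometry(geom$xmin - pad, geom$xmin - pad +
                        res_c * ceiling((geom$xmax - geom$xmin + 2 * pad) / res_c),
                      geom$ymin - pad, geom$ymin - pad +
                        res_c * ceiling((geom$ymax - geom$ymin + 2 * pad) / res_c),
                      res_c)
  vals <- local_seed(seed, matrix(stats::rnorm(cg$nrow * cg$ncol),
                                  cg$nrow, cg$ncol))
  resample_bilinear(geo_grid(vals, cg), geom)$values
}

#' Generate a synthetic world
#'
#' Monthly mean temperature follows
#' `eq_tmean - lapse*|lat| + amplitude*cos(2*pi*(m - phase(lat))/12)` plus
#' seeded noise, with the seasonal phase 6 months apart between
#' hemispheres; monthly minima are `tmean - diurnal_offset`. Precipitation
#' is a raised-cosine wet season centered on each hemisphere's summer,
#' scaled by an equator-to-edge taper, floored at the dry-season value and
#' perturbed by multiplicative lognormal noise. Soil pH is a smooth
#' spatially correlated field; countries are a contiguous rectangular
#' mosaic.
#'
#' @param spec A [world_spec()].
#' @return List with `stack` ([climate_stack()]), `ph` (`geo_grid`),
#'   `mosaic` ([region_mosaic()]), `spec`.
#' @export
make_world <- function(spec = world_spec()) {
  stopifnot(inherits(spec, "world_spec"))
  geom <- grid_geometry(spec$xmin, spec$xmax, spec$ymin, spec$ymax, spec$res)
  lat <- lat_centers(geom)
  nr <- geom$nrow; nc <- geom$ncol
  phase <- ifelse(lat >= 0, 7, 1)   # month of summer temperature peak
  tmean <- array(NA_real_, c(nr, nc, 12))
  prec <- array(NA_real_, c(nr, nc, 12))
  lat_edge <- max(abs(c(spec$ymin, spec$ymax)))
  taper <- 1 - spec$wet_taper * abs(lat) / lat_edge
  half <- spec$wet_months / 2
  for (m in 1:12) {
    tm_lat <- spec$eq_tmean - spec$lapse * abs(lat) +
      spec$amplitude * cos(2 * pi * (m - phase) / 12)
    tmean[, , m] <- matrix(tm_lat, nr, nc)
    # circular month distance to the hemisphere's wet-season center
    dm <- abs(((m - phase + 6) %% 12) - 6)
    wet <- ifelse(dm <= half, cos(pi * dm / (2 * half))^2, 0)
    pr_lat <- spec$dry_floor + (spec$wet_peak * taper - spec$dry_floor) *
      pmax(0, wet)
    prec[, , m] <- matrix(pmax(spec$dry_floor, pr_lat), nr, nc)
  }
  if (spec$t_noise_sd > 0)
    tmean <- tmean + local_seed(derive_seed(spec$seed, 1L),
      array(stats::rnorm(nr * nc * 12, sd = spec$t_noise_sd), c(nr, nc, 12)))
  if (spec$p_noise_sd > 0)
    prec <- prec * local_seed(derive_seed(spec$seed, 2L),
      array(stats::rlnorm(nr * nc * 12, sdlog = spec$p_noise_sd),
            c(nr, nc, 12)))
  tminm <- tmean - spec$diurnal_offset
  stack <- climate_stack(tmean, prec, tminm = tminm, geom = geom)

  z <- smooth_field(geom, spec$ph_corr_length, derive_seed(spec$seed, 3L))
  z <- (z - min(z)) / (max(z) - min(z))
  ph <- geo_grid(spec$ph_range[1] + z * diff(spec$ph_range), geom)

  k <- spec$n_countries
  ncol_blocks <- ceiling(sqrt(k))
  nrow_blocks <- ceiling(k / ncol_blocks)
  bi <- pmin(nrow_blocks, ceiling(seq_len(nr) / nr * nrow_blocks))
  bj <- pmin(ncol_blocks, ceiling(seq_len(nc) / nc * ncol_blocks))
  ids <- outer(bi, bj, function(i, j) (i - 1) * ncol_blocks + j)
  ids[ids > k] <- k  # fold the remainder block into the last country
  mosaic <- region_mosaic(ids, sprintf("country%02d", seq_len(k)), geom)
  list(stack = stack, ph = ph, mosaic = mosaic, spec = spec)
}

#' Ground-truth suitability of a synthetic world
#'
#' Runs the engine itself under the true generating parameters; the result
#' is the recovery target for calibration and validation tests.
#'
#' @param world A [make_world()] result.
#' @param p_true The generating [crop_parameters()].
#' @param cfg An [engine_config()].
#' @return A [suitability_map()].
#' @export
make_truth <- function(world, p_true, cfg = engine_config()) {
  map_suitability(world$stack, world$ph, p_true, cfg,
                  crop_code = p_true$crop_code, period = "curr")
}

#' Sample occurrence points from a truth map
#'
#' `n` points at cell centers sampled with probability proportional to
#' suitability, plus `round(background_rate * n)` uniform background points
#' on defined cells (emulating opportunistic-record noise).
#'
#' @param truth A [suitability_map()].
#' @param n Number of suitability-weighted points.
#' @param background_rate Background points as a fraction of `n`.
#' @param seed Integer seed.
#' @return An [occurrence_set()].
#' @export
sample_occurrences <- function(truth, n, background_rate = 0.05, seed = 1L) {
  stopifnot(n >= 1)
  v <- as.vector(truth$values)
  ok <- which(!is.na(v))
  if (sum(v[ok]) <= 0 && background_rate <= 0)
    stop("truth map has no positive suitability and no background rate")
  nb <- round(background_rate * n)
  cells <- local_seed(seed, {
    main <- sample(ok, n, replace = TRUE, prob = v[ok])
    bg <- if (nb > 0) sample(ok, nb, replace = TRUE) else integer(0)
    c(main, bg)
  })
  geom <- truth$geom
  row <- ((cells - 1) %% geom$nrow) + 1
  col <- ((cells - 1) %/% geom$nrow) + 1
  occurrence_set(lon = lon_centers(geom)[col], lat = lat_centers(geom)[row],
                 year = rep(2010L, length(cells)), provenance = "synthetic")
}

#' Synthetic harvested-area table
#'
#' Per country, harvested area = `0.3 x suitable area x lognormal(0, sd)`;
#' a `zero_fraction` of countries (chosen at random) is set to
#' non-producing. Emulates national harvested-area statistics in which the
#' realized niche is a noisy fraction of the fundamental one.
#'
#' @param binary Logical `geo_grid` of true suitability.
#' @param mosaic A [region_mosaic()].
#' @param noise_sd Lognormal sdlog of the per-country noise.
#' @param zero_fraction Fraction of countries set to non-producing.
#' @param seed Integer seed.
#' @param harvest_fraction Mean harvested / suitable ratio (default 0.3).
#' @return Data.frame `region_id`, `region_name`, `harvested_km2`.
#' @export
make_harvest_table <- function(binary, mosaic, noise_sd = 0.3,
                               zero_fraction = 0.2, seed = 1L,
                               harvest_fraction = 0.3) {
  stopifnot(zero_fraction >= 0, zero_fraction <= 1)
  suit <- suitable_area_by_region(binary, mosaic)
  k <- nrow(suit)
  harv <- local_seed(seed, {
    h <- harvest_fraction * suit$suitable_km2 *
      stats::rlnorm(k, 0, noise_sd)
    nz <- round(zero_fraction * k)
    if (nz > 0) h[sample(k, nz)] <- 0
    h
  })
  data.frame(region_id = suit$region_id, region_name = suit$region_name,
             harvested_km2 = harv, stringsAsFactors = FALSE)
}

#' Synthetic yield grid
#'
#' `yield = max(0, truth * (1 + N(0, sd)))` on defined cells; exactly 0
#' where the truth is 0 (no production outside the fundamental niche).
#'
#' @param truth A [suitability_map()].
#' @param noise_sd Gaussian noise sd (relative).
#' @param seed Integer seed.
#' @return A `geo_grid` of yields.
#' @export
make_yield_grid <- function(truth, noise_sd = 0.1, seed = 1L) {
  stopifnot(noise_sd >= 0)
  v <- truth$values
  noise <- local_seed(seed, matrix(stats::rnorm(length(v), 0, noise_sd),
                                   nrow(v), ncol(v)))
  y <- v * (1 + noise)
  y[which(y < 0)] <- 0
  y[which(v == 0)] <- 0
  geo_grid(y, truth$geom)
}
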