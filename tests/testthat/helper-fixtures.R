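# Shared fixtures and an independent scalar oracle for the engine.
# The oracle is deliberately written as plain per-cell/per-month loops with
# no shared code path with the vectorized engine.

test_params <- function(crop_code = "testcrop", crop_class = "Cereals",
                        gmin = 90, gmax = 120, ktmp = 0,
                        tmin = 10, topmin = 15, topmax = 25, tmax = 30,
                        rmin = 300, ropmin = 500, ropmax = 900, rmax = 1200,
                        phmin = 4.5, phopmin = 5.5, phopmax = 7, phmax = 8,
                        has_mapspam = TRUE, validate = TRUE) {
  crop_parameters(crop_code, crop_class, gmin, gmax, ktmp,
                  tmin, topmin, topmax, tmax, rmin, ropmin, ropmax, rmax,
                  phmin, phopmin, phopmax, phmax, has_mapspam, validate)
}

# a short-cycle tropical crop matched to the default synthetic world; its
# temperature and rainfall lower ramps are spatially aligned so marginal
# cells fall off quadratically (thin low-suitability tail -- see vignette)
demo_crop <- function() {
  crop_parameters("demo", "Cereals", gmin = 100, gmax = 140, ktmp = 0,
                  tmin = 16, topmin = 21.5, topmax = 30, tmax = 36,
                  rmin = 300, ropmin = 550, ropmax = 1000, rmax = 1600,
                  phmin = 3.5, phopmin = 4.6, phopmax = 8.4, phmax = 9.5)
}

# calibration recovery world and crop (frozen design; see methods vignette):
# low seasonal amplitude and a noise-gated rainfall boundary make each
# degraded parameter consequential and resolvable at the stated step sizes.
recovery_world_spec <- function(seed) {
  world_spec(xmin = 0, xmax = 20, ymin = -40, ymax = 40, res = 1,
             seed = seed, amplitude = 1, t_noise_sd = 0, wet_taper = 0,
             p_noise_sd = 0.01)
}

recovery_crop <- function() {
  crop_parameters("peren", "Banana", gmin = 300, gmax = 365, ktmp = 8,
                  tmin = 16, topmin = 16, topmax = 25.7, tmax = 25.7,
                  rmin = 1060, ropmin = 1060, ropmax = 1600, rmax = 2400,
                  phmin = 3, phopmin = 4.5, phopmax = 8.5, phmax = 9.5)
}

# graded-tent fixture for temperature-niche recovery: narrow perennial
# temperature tent on the seasonal default world, where a -2 degC shift
# costs enough accuracy (match ~0.68) that the offset search must move.
tent_world_spec <- function(seed) {
  world_spec(xmin = 0, xmax = 20, ymin = -40, ymax = 40, res = 1, seed = seed)
}

tent_crop <- function() {
  crop_parameters("tentcrop", "Banana", gmin = 300, gmax = 365, ktmp = 5,
                  tmin = 17, topmin = 21, topmax = 23, tmax = 27,
                  rmin = 450, ropmin = 460, ropmax = 1400, rmax = 2200,
                  phmin = 4, phopmin = 5, phopmax = 7.5, phmax = 8.8)
}

degrade_params <- function(p, rain = 30, niche = -2) {
  p$rmin <- p$rmin + rain; p$ropmin <- p$ropmin + rain
  for (f in c("tmin", "topmin", "topmax", "tmax")) p[[f]] <- p[[f]] + niche
  p
}

# random small world with fully random (unstructured) climate layers
random_world <- function(seed, nr = 5, nc = 5, with_tminm = TRUE) {
  geom <- grid_geometry(0, nc * 0.5, 0, nr * 0.5, 0.5)
  local_seed(seed, {
    tmean <- array(runif(nr * nc * 12, 5, 35), c(nr, nc, 12))
    tminm <- if (with_tminm) tmean - runif(nr * nc * 12, 0, 10) else NULL
    prec <- array(rgamma(nr * nc * 12, shape = 2, scale = 60), c(nr, nc, 12))
    ph <- geo_grid(matrix(runif(nr * nc, 4, 9), nr, nc), geom)
    list(stack = climate_stack(tmean, prec, tminm = tminm, geom = geom),
         ph = ph)
  })
}

# ---- independent scalar oracle --------------------------------------------

oracle_trap <- function(x, a, o1, o2, b) {
  if (is.na(x)) return(NA_real_)
  if (x <= a && !(x >= o1)) return(0)
  if (x >= b && !(x <= o2)) return(0)
  if (x >= o1 && x <= o2) return(1)
  if (x < o1) return((x - a) / (o1 - a))
  (b - x) / (b - o2)
}

oracle_cell <- function(tmean, prec, ph, p, cfg, tminm = NULL) {
  dur <- floor((p$gmin + p$gmax) / 60 + 0.5)
  dur <- min(12, max(1, dur))
  comb <- function(a, b, rule) {
    if (is.na(a) || is.na(b)) return(NA_real_)
    if (rule == "product") a * b else min(a, b)
  }
  best <- NA_real_
  for (s in 1:12) {
    months <- ((s - 1 + 0:(dur - 1)) %% 12) + 1
    tsc <- Inf
    for (m in months) {
      sm <- oracle_trap(tmean[m], p$tmin, p$topmin, p$topmax, p$tmax)
      kt <- if (is.null(tminm)) tmean[m] else tminm[m]
      if (is.na(sm) || is.na(kt)) { tsc <- NA_real_; break }
      if (kt < p$ktmp + cfg$frost_buffer) sm <- 0
      tsc <- min(tsc, sm)
    }
    rtot <- 0
    for (m in months) rtot <- rtot + prec[m]
    rsc <- oracle_trap(rtot, p$rmin, p$ropmin, p$ropmax, p$rmax)
    sc <- comb(tsc, rsc, cfg$combine_rule)
    if (!is.na(sc) && (is.na(best) || sc > best)) best <- sc
  }
  comb(best, oracle_trap(ph, p$phmin, p$phopmin, p$phopmax, p$phmax),
       cfg$ph_rule)
}

oracle_map <- function(stack, ph, p, cfg = engine_config()) {
  nr <- stack$geom$nrow; nc <- stack$geom$ncol
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!stack$land_mask[i, j]) next
    out[i, j] <- oracle_cell(stack$tmean[i, j, ], stack$prec[i, j, ],
                             ph$values[i, j], p, cfg,
                             if (is.null(stack$tminm)) NULL else
                               stack$tminm[i, j, ])
  }
  out
}

# brute-force Se=Sp scan oracle
oracle_equalize <- function(scores, labels) {
  cand <- sort(unique(c(0, 1, scores)))
  best <- NULL
  for (t in cand) {
    pred <- scores >= t
    se <- sum(pred & labels) / sum(labels)
    sp <- sum(!pred & !labels) / sum(!labels)
    gap <- abs(se - sp)
    if (is.null(best) || gap < best$gap - 1e-12 ||
        (abs(gap - best$gap) <= 1e-12 && se + sp > best$se + best$sp + 1e-12))
      best <- list(threshold = t, se = se, sp = sp, gap = gap)
  }
  best
}
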