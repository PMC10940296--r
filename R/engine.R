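# The mechanistic suitability engine. Per cell, every growing window
# starting at each of the 12 calendar months is scored; the best window's
# climate score, combined with soil-pH suitability, is the cell's [0,1]
# suitability index. Only one season is kept (no double-cropping
# accumulation). The grid path is vectorized over cells; tests check it
# against an independent scalar loop.

#' Engine configuration
#'
#' @param combine_rule How monthly-temperature and seasonal-rainfall scores
#'   combine: `"product"` (default, preserves gradation) or `"min"`.
#' @param ph_rule How the climate score combines with soil-pH suitability:
#'   `"product"` (default) or `"min"`.
#' @param frost_buffer Safety margin (degC) added to the kill temperature in
#'   the frost test; a window month is killed when its test temperature
#'   (monthly minimum when available, else monthly mean) falls below
#'   `ktmp + frost_buffer`. Default 4.
#' @return An `engine_config` list.
#' @export
engine_config <- function(combine_rule = c("product", "min"),
                          ph_rule = c("product", "min"),
                          frost_buffer = 4) {
  combine_rule <- match.arg(combine_rule)
  ph_rule <- match.arg(ph_rule)
  stopifnot(is.numeric(frost_buffer), frost_buffer >= 0)
  structure(list(combine_rule = combine_rule, ph_rule = ph_rule,
                 frost_buffer = frost_buffer), class = "engine_config")
}

combine2 <- function(a, b, rule) if (rule == "product") a * b else pmin(a, b)

#' Trapezoidal membership function
#'
#' 0 at or outside the absolute bounds, 1 on the optimal plateau, linear on
#' the two ramps. Degenerate equal bounds (e.g. `amin == omin`) act as a
#' step at that bound.
#'
#' @param x Value(s) to score; vectorized, `NA` propagates.
#' @param amin,omin,omax,amax Absolute-min, optimal-min, optimal-max,
#'   absolute-max bounds; must be ordered `amin <= omin <= omax <= amax`.
#' @return Score(s) in `[0, 1]`.
#' @examples
#' trapezoid_suitability(c(5, 10, 17.5, 25, 40), 10, 15, 30, 35)
#' @export
trapezoid_suitability <- function(x, amin, omin, omax, amax) {
  if (amin > omin || omin > omax || omax > amax)
    stop("trapezoid bounds must satisfy amin <= omin <= omax <= amax")
  s <- numeric(length(x))
  s[which(x >= omin & x <= omax)] <- 1
  lo <- x > amin & x < omin
  if (any(lo, na.rm = TRUE)) s[which(lo)] <- (x[which(lo)] - amin) / (omin - amin)
  hi <- x > omax & x < amax
  if (any(hi, na.rm = TRUE)) s[which(hi)] <- (amax - x[which(hi)]) / (amax - omax)
  s[is.na(x)] <- NA_real_
  s
}

#' Growing-season duration in months
#'
#' `round_half_up((gmin + gmax) / 60)` months, clamped to 1..12: the
#' midpoint of the crop's growth-cycle length range, converted to whole
#' months.
#'
#' @param p A [crop_parameters()].
#' @return Integer number of window months, 1..12.
#' @examples
#' p <- crop_parameters("demo", "Cereals", 90, 120, 0, 10, 15, 25, 30,
#'                      300, 500, 900, 1200, 5, 5.5, 7, 8)
#' duration_months(p)  # 210/60 = 3.5 -> 4
#' @export
duration_months <- function(p) {
  d <- floor((p$gmin + p$gmax) / 60 + 0.5)  # half-up, not banker's rounding
  as.integer(min(12, max(1, d)))
}

#' Months of a growing window
#'
#' @param start_month Start month, 1..12.
#' @param duration Window length in months, 1..12.
#' @return `duration` consecutive month indices with December -> January
#'   wrap-around.
#' @examples
#' growing_window(11, 4)  # 11 12 1 2
#' @export
growing_window <- function(start_month, duration) {
  stopifnot(start_month %in% 1:12)
  if (duration < 1 || duration > 12) stop("duration must be in 1..12")
  as.integer(((start_month - 1 + seq_len(duration) - 1) %% 12) + 1)
}

#' Seasonal temperature suitability for one cell
#'
#' Each window month is scored on the mean-temperature trapezoid and forced
#' to 0 if the month's kill-test temperature (monthly minimum when
#' supplied, else the monthly mean) is below `ktmp + frost_buffer`; the
#' window score is the minimum over its months (one bad month breaks the
#' season).
#'
#' @param tmean 12-vector of monthly mean temperatures, degC.
#' @param p A [crop_parameters()].
#' @param window Month indices from [growing_window()].
#' @param cfg An [engine_config()].
#' @param tminm Optional 12-vector of monthly minimum temperatures.
#' @return Score in `[0, 1]`; `NA` if any window month is missing.
#' @export
temp_suitability_season <- function(tmean, p, window, cfg = engine_config(),
                                    tminm = NULL) {
  tm <- tmean[window]
  if (anyNA(tm)) return(NA_real_)
  s <- trapezoid_suitability(tm, p$tmin, p$topmin, p$topmax, p$tmax)
  kill_t <- if (is.null(tminm)) tm else tminm[window]
  if (anyNA(kill_t)) return(NA_real_)
  s[kill_t < p$ktmp + cfg$frost_buffer] <- 0
  min(s)
}

#' Seasonal rainfall suitability for one cell
#'
#' The window's precipitation total scored on the seasonal-rainfall
#' trapezoid.
#'
#' @param prec 12-vector of monthly precipitation sums, mm.
#' @inheritParams temp_suitability_season
#' @return Score in `[0, 1]`; `NA` if any window month is missing.
#' @export
rain_suitability_season <- function(prec, p, window) {
  pr <- prec[window]
  if (anyNA(pr)) return(NA_real_)
  trapezoid_suitability(sum(pr), p$rmin, p$ropmin, p$ropmax, p$rmax)
}

#' Soil pH suitability
#'
#' @param ph Soil pH value(s); vectorized, `NA` propagates (cells with
#'   missing pH stay missing rather than being treated as unconstrained).
#' @param p A [crop_parameters()].
#' @return Score(s) in `[0, 1]`.
#' @export
ph_suitability <- function(ph, p) {
  trapezoid_suitability(ph, p$phmin, p$phopmin, p$phopmax, p$phmax)
}

#' Suitability of a single cell
#'
#' Maximizes `combine(temperature, rainfall)` over the 12 candidate start
#' months, then combines with pH suitability under the configured rule.
#'
#' @param tmean,prec 12-vectors of monthly climate; `tminm` optional.
#' @param ph Scalar soil pH.
#' @param p A [crop_parameters()].
#' @param cfg An [engine_config()].
#' @param tminm Optional 12-vector of monthly minima.
#' @return Score in `[0, 1]`, or `NA` when inputs are missing.
#' @export
cell_suitability <- function(tmean, prec, ph, p, cfg = engine_config(),
                             tminm = NULL) {
  d <- duration_months(p)
  best <- NA_real_
  for (s in 1:12) {
    w <- growing_window(s, d)
    ts <- temp_suitability_season(tmean, p, w, cfg, tminm)
    rs <- rain_suitability_season(prec, p, w)
    sc <- combine2(ts, rs, cfg$combine_rule)
    if (!is.na(sc) && (is.na(best) || sc > best)) best <- sc
  }
  combine2(best, ph_suitability(ph, p), cfg$ph_rule)
}

#' Tagged suitability map
#'
#' @param values Score matrix in `[0,1]` (NA = missing).
#' @param geom A [grid_geometry()].
#' @param crop_code,period,model Archive metadata tokens.
#' @return A `suitability_map` (also a `geo_grid`).
#' @export
suitability_map <- function(values, geom, crop_code = NA_character_,
                            period = NA_character_, model = NA_character_) {
  g <- geo_grid(values, geom)
  if (any(g$values < -1e-12 | g$values > 1 + 1e-12, na.rm = TRUE))
    stop("suitability values must lie in [0, 1]")
  g$meta <- list(crop_code = crop_code, period = period, model = model)
  class(g) <- c("suitability_map", "geo_grid")
  g
}

#' Map suitability over a climate stack
#'
#' Vectorized application of [cell_suitability()] to every land cell of a
#' [climate_stack()]; non-land and missing cells propagate as `NA`.
#'
#' @param stack A [climate_stack()].
#' @param ph A `geo_grid` of soil pH on the stack geometry.
#' @param p A [crop_parameters()].
#' @param cfg An [engine_config()].
#' @param crop_code,period,model Metadata tokens stamped on the result.
#' @return A [suitability_map()].
#' @export
map_suitability <- function(stack, ph, p, cfg = engine_config(),
                            crop_code = p$crop_code, period = NA_character_,
                            model = NA_character_) {
  stopifnot(inherits(stack, "climate_stack"), inherits(ph, "geo_grid"))
  if (!same_geometry(stack$geom, ph$geom))
    stop("pH grid geometry does not match the climate stack")
  n <- stack$geom$nrow * stack$geom$ncol
  TM <- matrix(stack$tmean, n, 12)
  PR <- matrix(stack$prec, n, 12)
  KT <- if (is.null(stack$tminm)) TM else matrix(stack$tminm, n, 12)

  # month scores with kill test applied once, then window minima / sums
  S <- matrix(trapezoid_suitability(as.vector(TM),
                                    p$tmin, p$topmin, p$topmax, p$tmax), n, 12)
  S[which(KT < p$ktmp + cfg$frost_buffer)] <- 0
  d <- duration_months(p)
  best <- NULL
  for (s0 in 1:12) {
    w <- growing_window(s0, d)
    ts <- do.call(pmin, lapply(w, function(m) S[, m]))
    rtot <- if (length(w) == 1L) PR[, w] else rowSums(PR[, w, drop = FALSE])
    rs <- trapezoid_suitability(rtot, p$rmin, p$ropmin, p$ropmax, p$rmax)
    sc <- combine2(ts, rs, cfg$combine_rule)
    best <- if (is.null(best)) sc else pmax(best, sc)  # NA propagates
  }
  phs <- trapezoid_suitability(as.vector(ph$values),
                               p$phmin, p$phopmin, p$phopmax, p$phmax)
  vals <- combine2(best, phs, cfg$ph_rule)
  vals[!as.vector(stack$land_mask)] <- NA_real_
  suitability_map(matrix(vals, stack$geom$nrow, stack$geom$ncol),
                  stack$geom, crop_code, period, model)
}
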