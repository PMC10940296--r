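# The six-metric evaluation framework: occurrence-point detection,
# country-level detection / correlation / area-exceedance against
# FAOSTAT-style and MAPSPAM-style harvested-area tables, and the
# threshold-exceedance profiles summarizing them per crop and crop class.

#' Occurrence point set
#'
#' @param lon,lat Point coordinates, decimal degrees.
#' @param year Optional integer years.
#' @param provenance Free-text source tag.
#' @return An `occurrence_set` data.frame with attribute `provenance`.
#' @export
occurrence_set <- function(lon, lat, year = NULL, provenance = "synthetic") {
  stopifnot(length(lon) == length(lat))
  d <- data.frame(
    lon = lon, lat = lat,
    year = if (is.null(year)) rep(NA_integer_, length(lon))
           else as.integer(year))
  attr(d, "provenance") <- provenance
  class(d) <- c("occurrence_set", "data.frame")
  d
}

#' Filter occurrences by year
#'
#' Keeps points with `year >= min_year` (points without a year are kept),
#' matching the baseline-period filter applied to occurrence archives.
#'
#' @param points An [occurrence_set()].
#' @param min_year Earliest year retained (default 2000).
#' @return Filtered `occurrence_set`.
#' @export
filter_occurrences_by_year <- function(points, min_year = 2000) {
  keep <- is.na(points$year) | points$year >= min_year
  out <- points[keep, , drop = FALSE]
  class(out) <- class(points); attr(out, "provenance") <- attr(points, "provenance")
  out
}

point_cell_index <- function(points, geom) {
  col <- floor((points$lon - geom$xmin) / geom$res) + 1
  row <- floor((geom$ymax - points$lat) / geom$res) + 1
  inside <- col >= 1 & col <= geom$ncol & row >= 1 & row <= geom$nrow
  list(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Thin occurrences to one point per grid cell
#'
#' Keeps at most one point per grid cell, chosen uniformly at random with
#' the given seed; points outside the grid are dropped and counted in the
#' `n_dropped_offgrid` attribute.
#'
#' @param points An [occurrence_set()].
#' @param geom A [grid_geometry()].
#' @param seed Integer RNG seed (required: thinning must be reproducible).
#' @return Thinned `occurrence_set`.
#' @export
thin_to_grid <- function(points, geom, seed) {
  stopifnot(!missing(seed))
  idx <- point_cell_index(points, geom)
  kept <- points[idx$inside, , drop = FALSE]
  n_off <- sum(!idx$inside)
  if (nrow(kept)) {
    cell <- (idx$row[idx$inside] - 1) * geom$ncol + idx$col[idx$inside]
    pick <- local_seed(seed, {
      unlist(lapply(split(seq_len(nrow(kept)), cell), function(ix)
        if (length(ix) == 1L) ix else sample(ix, 1L)))
    })
    kept <- kept[sort(pick), , drop = FALSE]
  }
  class(kept) <- class(points)
  attr(kept, "provenance") <- attr(points, "provenance")
  attr(kept, "n_dropped_offgrid") <- n_off
  kept
}

#' Occurrence detection rate
#'
#' Proportion of points falling in suitable cells of a binary map. Points
#' in missing cells stay in the denominator and are reported via the
#' `n_missing_cells` attribute.
#'
#' @param points A thinned [occurrence_set()].
#' @param binary Logical `geo_grid`.
#' @return Proportion in `[0, 1]` with attribute `n_missing_cells`.
#' @export
occurrence_detection_rate <- function(points, binary) {
  stopifnot(inherits(binary, "geo_grid"))
  if (!nrow(points)) stop("no occurrence points to evaluate")
  idx <- point_cell_index(points, binary$geom)
  vals <- rep(NA, nrow(points))
  vals[idx$inside] <- binary$values[cbind(idx$row[idx$inside],
                                          idx$col[idx$inside])]
  rate <- sum(vals, na.rm = TRUE) / nrow(points)
  attr(rate, "n_missing_cells") <- sum(is.na(vals))
  rate
}

#' Country-level table for area-based validation
#'
#' @param region_id,region_name Region identifiers.
#' @param harvested_km2 Reported harvested area per region (>= 0).
#' @param suitable_km2 Modelled suitable area per region (>= 0).
#' @param source Source tag, e.g. `"faostat"` or `"mapspam"`.
#' @return A `country_table` data.frame with a derived `produced` flag
#'   (`harvested_km2 > 0`).
#' @export
country_table <- function(region_id, region_name, harvested_km2,
                          suitable_km2, source = "faostat") {
  stopifnot(all(harvested_km2 >= 0, na.rm = TRUE),
            all(suitable_km2 >= 0, na.rm = TRUE))
  d <- data.frame(region_id = region_id, region_name = region_name,
                  produced = !is.na(harvested_km2) & harvested_km2 > 0,
                  harvested_km2 = harvested_km2,
                  suitable_km2 = suitable_km2,
                  source = source, stringsAsFactors = FALSE)
  class(d) <- c("country_table", "data.frame")
  d
}

#' Country detection accuracy
#'
#' A country mismatches only when the crop is reported as produced there
#' but the modelled suitable area is at most one grid cell; non-producing
#' countries may legitimately be suitable (the fundamental niche exceeds
#' the realized one) and always count as matches. When no country produces
#' the crop the metric is degenerate (trivially 1) and flagged via the
#' `degenerate` attribute.
#'
#' @param table A [country_table()].
#' @param one_cell_area_km2 Area bar: one grid cell's area, km^2 (e.g.
#'   [cell_area_km2()] at the region's mean latitude).
#' @return Proportion matched in `[0, 1]`.
#' @export
country_detection_accuracy <- function(table, one_cell_area_km2) {
  if (!nrow(table)) stop("empty country table")
  mismatch <- table$produced & table$suitable_km2 <= one_cell_area_km2
  acc <- mean(!mismatch)
  attr(acc, "degenerate") <- !any(table$produced)
  acc
}

#' Harvested-vs-suitable area correlation
#'
#' Pearson correlation of reported harvested area against modelled
#' suitable area across countries; positive correlation is the acceptance
#' direction. Optionally on log1p-transformed areas.
#'
#' @param table A [country_table()].
#' @param log_areas Correlate `log1p(area)` instead of raw areas
#'   (default `FALSE`).
#' @return Correlation in `[-1, 1]`, or `NA` with a `reason` attribute when
#'   fewer than 3 complete pairs or zero variance.
#' @export
area_correlation <- function(table, log_areas = FALSE) {
  h <- table$harvested_km2; s <- table$suitable_km2
  ok <- !is.na(h) & !is.na(s)
  if (sum(ok) < 3) {
    r <- NA_real_; attr(r, "reason") <- "fewer than 3 complete pairs"
    return(r)
  }
  h <- h[ok]; s <- s[ok]
  if (log_areas) { h <- log1p(h); s <- log1p(s) }
  if (stats::sd(h) == 0 || stats::sd(s) == 0) {
    r <- NA_real_; attr(r, "reason") <- "zero variance"
    return(r)
  }
  stats::cor(h, s)
}

#' Suitable-area exceedance proportion
#'
#' Proportion of countries whose modelled suitable area strictly exceeds
#' the reported harvested area (the fundamental niche should bound the
#' realized niche from above).
#'
#' @param table A [country_table()].
#' @return Proportion in `[0, 1]`.
#' @export
area_exceedance <- function(table) {
  ok <- !is.na(table$harvested_km2) & !is.na(table$suitable_km2)
  if (!any(ok)) stop("no country with both areas defined")
  mean(table$suitable_km2[ok] > table$harvested_km2[ok])
}

#' Six-metric report row for one crop
#'
#' @param gbif_detection,faostat_detection,faostat_correlation,
#'   faostat_exceedance,mapspam_correlation,mapspam_exceedance The six
#'   metrics; `NA` where the reference is unavailable.
#' @return Named numeric vector of length 6.
#' @export
metric_report_row <- function(gbif_detection, faostat_detection,
                              faostat_correlation, faostat_exceedance,
                              mapspam_correlation = NA_real_,
                              mapspam_exceedance = NA_real_) {
  c(gbif_detection = as.numeric(gbif_detection),
    faostat_detection = as.numeric(faostat_detection),
    faostat_correlation = as.numeric(faostat_correlation),
    faostat_exceedance = as.numeric(faostat_exceedance),
    mapspam_correlation = as.numeric(mapspam_correlation),
    mapspam_exceedance = as.numeric(mapspam_exceedance))
}

#' Threshold-exceedance profile of a metric vector
#'
#' For each threshold, the number of defined metrics strictly above it
#' (at most 6, the number of metrics; non-increasing in the threshold).
#'
#' @param metrics Numeric vector of up to 6 metrics (`NA` never counts).
#' @param thresholds Thresholds profiled (default 0.5..0.9).
#' @return Named integer vector of counts per threshold.
#' @examples
#' threshold_profile(c(0.95, 0.95, 0.8, 0.75, 0.6, 0.55))
#' @export
threshold_profile <- function(metrics, thresholds = seq(0.5, 0.9, 0.1)) {
  stopifnot(length(metrics) <= 6)
  counts <- vapply(thresholds, function(t) sum(metrics > t, na.rm = TRUE), 0L)
  names(counts) <- formatC(thresholds, format = "g")
  counts
}

#' Mean exceedance profile per crop class
#'
#' @param profiles Named list of [threshold_profile()] vectors, one per
#'   crop (names = crop codes present in the registry).
#' @param registry A [load_registry()] result.
#' @return Matrix: rows = crop classes, columns = thresholds, values =
#'   mean counts.
#' @export
class_mean_profile <- function(profiles, registry) {
  codes <- names(profiles)
  unknown <- setdiff(codes, names(registry$entries))
  if (length(unknown)) stop("unknown crop code(s): ",
                            paste(unknown, collapse = ", "))
  cls <- vapply(codes, function(cc) registry$entries[[cc]]$crop_class, "")
  mat <- do.call(rbind, profiles)
  classes <- sort(unique(cls))
  out <- do.call(rbind, lapply(classes, function(k)
    colMeans(mat[cls == k, , drop = FALSE])))
  rownames(out) <- classes
  out
}

#' Run the six-metric evaluation for one crop
#'
#' Convenience wrapper tying the pieces together: thins the occurrence
#' points, computes the detection rate on the binary map, aggregates the
#' modelled suitable area per region, and scores the FAOSTAT-style and
#' (when available) MAPSPAM-style country tables.
#'
#' @param binary Logical `geo_grid` (the binarized suitability map).
#' @param points An [occurrence_set()].
#' @param mosaic A [region_mosaic()].
#' @param faostat,mapspam Data.frames with `region_id`, `harvested_km2`
#'   (MAPSPAM optional: `NULL` when the crop lacks coverage).
#' @param seed Seed for point thinning.
#' @return A [metric_report_row()] with attribute `table` (the assembled
#'   [country_table()] for the FAOSTAT-style source).
#' @export
evaluate_crop <- function(binary, points, mosaic, faostat, mapspam = NULL,
                          seed = 1L) {
  suit <- suitable_area_by_region(binary, mosaic)
  thin <- thin_to_grid(filter_occurrences_by_year(points), binary$geom, seed)
  gbif <- as.numeric(occurrence_detection_rate(thin, binary))
  lat_bar <- mean(abs(lat_centers(binary$geom)))
  one_cell <- cell_area_km2(lat_bar, binary$geom$res)
  mk_table <- function(ref, src) {
    m <- merge(suit, ref[, c("region_id", "harvested_km2")],
               by = "region_id", all.x = TRUE)
    country_table(m$region_id, m$region_name,
                  ifelse(is.na(m$harvested_km2), 0, m$harvested_km2),
                  m$suitable_km2, source = src)
  }
  ft <- mk_table(faostat, "faostat")
  row <- metric_report_row(
    gbif_detection = gbif,
    faostat_detection = as.numeric(country_detection_accuracy(ft, one_cell)),
    faostat_correlation = as.numeric(area_correlation(ft)),
    faostat_exceedance = area_exceedance(ft))
  if (!is.null(mapspam)) {
    mt <- mk_table(mapspam, "mapspam")
    row["mapspam_correlation"] <- as.numeric(area_correlation(mt))
    row["mapspam_exceedance"] <- area_exceedance(mt)
  }
  attr(row, "table") <- ft
  row
}
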