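# Regular lat-lon grids, cell-center registered, rows north -> south.
# All layers in the pipeline share one `grid_geometry`; values live in plain
# matrices (nrow = latitude rows, ncol = longitude columns) so the package
# has no geospatial-stack dependency.

#' Define a regular lat-lon grid geometry
#'
#' Grids are cell-center registered on WGS84-style geographic coordinates,
#' with rows ordered north to south and columns west to east (the order in
#' which raster files are written).
#'
#' @param xmin,xmax,ymin,ymax Grid edges in decimal degrees.
#' @param res Cell size in degrees (same in both axes); must divide the
#'   extent in both directions.
#' @return A `grid_geometry` object with derived `nrow`, `ncol`.
#' @examples
#' g <- grid_geometry(0, 10, -5, 5, res = 0.5)
#' g$nrow; g$ncol
#' @export
grid_geometry <- function(xmin, xmax, ymin, ymax, res = 0.5) {
  stopifnot(xmax > xmin, ymax > ymin, res > 0)
  nx <- (xmax - xmin) / res
  ny <- (ymax - ymin) / res
  if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8)
    stop("resolution must divide the extent in both directions")
  structure(
    list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
         res = res, nrow = as.integer(round(ny)), ncol = as.integer(round(nx))),
    class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d cells at %g deg, lon [%g, %g], lat [%g, %g]\n",
              x$nrow, x$ncol, x$res, x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

#' Cell-center coordinates of a grid geometry
#'
#' @param geom A [grid_geometry()].
#' @return `lat_centers()`: latitudes by row (north to south);
#'   `lon_centers()`: longitudes by column (west to east).
#' @export
lat_centers <- function(geom) {
  geom$ymax - geom$res / 2 - (seq_len(geom$nrow) - 1) * geom$res
}

#' @rdname lat_centers
#' @export
lon_centers <- function(geom) {
  geom$xmin + geom$res / 2 + (seq_len(geom$ncol) - 1) * geom$res
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(abs(c(a$xmin - b$xmin, a$xmax - b$xmax, a$ymin - b$ymin,
            a$ymax - b$ymax, a$res - b$res)) < tol)
}

#' A single gridded layer
#'
#' @param values Numeric (or logical) matrix, `geom$nrow` x `geom$ncol`,
#'   rows north to south. `NA` marks missing / non-land cells.
#' @param geom A [grid_geometry()].
#' @return A `geo_grid` object.
#' @export
geo_grid <- function(values, geom) {
  stopifnot(inherits(geom, "grid_geometry"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(geom$nrow, geom$ncol)))
    stop(sprintf("values must be %d x %d to match the geometry",
                 geom$nrow, geom$ncol))
  structure(list(values = values, geom = geom), class = "geo_grid")
}

#' @export
print.geo_grid <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("geo_grid %d x %d, values in [%g, %g], %d missing\n",
              x$geom$nrow, x$geom$ncol, rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' Monthly climatology stack
#'
#' Bundles the 12-month climatologies the suitability engine consumes:
#' monthly mean temperature (degC), optional monthly minimum temperature
#' (degC, used for the frost kill test when present) and monthly
#' precipitation sums (mm), plus a land mask. All layers share one geometry;
#' masked cells carry `NA` that propagates through the engine.
#'
#' @param tmean,prec Numeric arrays `nrow x ncol x 12`.
#' @param tminm Optional `nrow x ncol x 12` array of monthly minimum
#'   temperature; must be `<= tmean` cell-wise where both are defined.
#' @param land_mask Logical matrix; `FALSE` cells are set to `NA` in all
#'   layers.
#' @param geom A [grid_geometry()].
#' @return A `climate_stack` object.
#' @export
climate_stack <- function(tmean, prec, tminm = NULL, land_mask = NULL, geom) {
  stopifnot(inherits(geom, "grid_geometry"))
  dims <- c(geom$nrow, geom$ncol, 12L)
  chk <- function(a, nm) {
    if (!is.array(a) || !all(dim(a) == dims))
      stop(sprintf("%s must be an array of dim %d x %d x 12", nm,
                   geom$nrow, geom$ncol))
    a
  }
  tmean <- chk(tmean, "tmean"); prec <- chk(prec, "prec")
  if (!is.null(tminm)) tminm <- chk(tminm, "tminm")
  if (is.null(land_mask)) land_mask <- matrix(TRUE, geom$nrow, geom$ncol)
  stopifnot(is.logical(land_mask), all(dim(land_mask) == dims[1:2]))
  na_cells <- !land_mask
  if (any(na_cells)) {
    idx <- which(rep(na_cells, 12L))
    tmean[idx] <- NA_real_; prec[idx] <- NA_real_
    if (!is.null(tminm)) tminm[idx] <- NA_real_
  }
  if (any(prec < -1e-9, na.rm = TRUE))
    stop("precipitation must be non-negative")
  if (!is.null(tminm) && any(tminm > tmean + 1e-9, na.rm = TRUE))
    stop("tminm must not exceed tmean")
  structure(list(tmean = tmean, tminm = tminm, prec = prec,
                 land_mask = land_mask, geom = geom),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack %d x %d x 12 (%s tminm), %d land cells\n",
              x$geom$nrow, x$geom$ncol,
              if (is.null(x$tminm)) "no" else "with", sum(x$land_mask)))
  invisible(x)
}

#' Spherical area of a grid cell
#'
#' Area of a `res` x `res` degree cell centered at latitude `lat_center` on
#' a sphere of radius 6371 km: `R^2 * dlambda * (sin(phi_top) - sin(phi_bot))`.
#'
#' @param lat_center Cell-center latitude(s), degrees; vectorized.
#' @param res Cell size, degrees.
#' @return Area(s) in km^2.
#' @examples
#' cell_area_km2(0.25, 0.5)  # ~3091 km^2
#' @export
cell_area_km2 <- function(lat_center, res = 0.5) {
  if (any(abs(lat_center) + res / 2 > 90 + 1e-9))
    stop("cell extends beyond +/-90 degrees latitude")
  R <- 6371
  top <- (lat_center + res / 2) * pi / 180
  bot <- (lat_center - res / 2) * pi / 180
  R^2 * (res * pi / 180) * (sin(top) - sin(bot))
}

#' Per-row cell areas for a geometry
#'
#' @param geom A [grid_geometry()].
#' @return Matrix of cell areas (km^2) matching the grid shape.
#' @export
cell_area_grid <- function(geom) {
  matrix(cell_area_km2(lat_centers(geom), geom$res),
         nrow = geom$nrow, ncol = geom$ncol)
}

#' Region mosaic: integer country labels on the grid
#'
#' @param ids Integer matrix of region ids (`NA` = unassigned) on `geom`.
#' @param names Character vector of region names, indexed by id.
#' @param geom A [grid_geometry()].
#' @return A `region_mosaic` object.
#' @export
region_mosaic <- function(ids, names, geom) {
  stopifnot(inherits(geom, "grid_geometry"),
            all(dim(ids) == c(geom$nrow, geom$ncol)))
  ids <- matrix(as.integer(ids), geom$nrow, geom$ncol)
  present <- sort(unique(ids[!is.na(ids)]))
  if (length(present) && max(present) > length(names))
    stop("region id exceeds the name table")
  structure(list(ids = ids, names = names, geom = geom),
            class = "region_mosaic")
}

#' Suitable area per region
#'
#' Sums spherical cell areas over suitable cells within each region of a
#' mosaic. Regions with no suitable cell report 0.
#'
#' @param binary A logical `geo_grid` (TRUE = suitable; `NA` ignored).
#' @param mosaic A [region_mosaic()] on the same geometry.
#' @return A data.frame with `region_id`, `region_name`, `suitable_km2`,
#'   one row per region in the mosaic's name table.
#' @export
suitable_area_by_region <- function(binary, mosaic) {
  stopifnot(inherits(binary, "geo_grid"), inherits(mosaic, "region_mosaic"))
  if (!same_geometry(binary$geom, mosaic$geom))
    stop("binary map and mosaic geometries differ")
  area <- cell_area_grid(binary$geom)
  suit <- binary$values
  ok <- !is.na(suit) & suit & !is.na(mosaic$ids)
  sums <- tapply(area[ok], mosaic$ids[ok], sum)
  out <- data.frame(region_id = seq_along(mosaic$names),
                    region_name = mosaic$names,
                    suitable_km2 = 0, stringsAsFactors = FALSE)
  if (length(sums))
    out$suitable_km2[as.integer(names(sums))] <- as.numeric(sums)
  out
}

#' Bilinear resampling between regular lat-lon grids
#'
#' Interpolates from the four surrounding source cell centers; destination
#' points beyond the source center lattice take the nearest-edge value
#' (constant extrapolation). Reproduces affine fields exactly at interior
#' points.
#'
#' @param src A `geo_grid` to resample.
#' @param dst_geom Target [grid_geometry()]; must overlap the source extent.
#' @return A `geo_grid` on `dst_geom`.
#' @export
resample_bilinear <- function(src, dst_geom) {
  stopifnot(inherits(src, "geo_grid"), inherits(dst_geom, "grid_geometry"))
  if (dst_geom$xmin >= src$geom$xmax || dst_geom$xmax <= src$geom$xmin ||
      dst_geom$ymin >= src$geom$ymax || dst_geom$ymax <= src$geom$ymin)
    stop("destination extent does not overlap the source grid")
  sx <- lon_centers(src$geom)            # ascending
  sy <- rev(lat_centers(src$geom))       # ascending for interpolation
  v <- src$values[src$geom$nrow:1, , drop = FALSE]  # row 1 = southmost
  dx <- lon_centers(dst_geom)
  dy <- rev(lat_centers(dst_geom))

  ix <- findInterval(dx, sx, rightmost.closed = FALSE, all.inside = TRUE)
  iy <- findInterval(dy, sy, rightmost.closed = FALSE, all.inside = TRUE)
  # fractional position, clamped so off-lattice points use the edge value
  fx <- pmin(1, pmax(0, (dx - sx[ix]) / (sx[ix + 1] - sx[ix])))
  fy <- pmin(1, pmax(0, (dy - sy[iy]) / (sy[iy + 1] - sy[iy])))

  FX <- matrix(fx, length(dy), length(dx), byrow = TRUE)
  FY <- matrix(fy, length(dy), length(dx))
  v11 <- v[cbind(rep(iy, length(dx)), rep(ix, each = length(dy)))]
  v21 <- v[cbind(rep(iy + 1, length(dx)), rep(ix, each = length(dy)))]
  v12 <- v[cbind(rep(iy, length(dx)), rep(ix + 1, each = length(dy)))]
  v22 <- v[cbind(rep(iy + 1, length(dx)), rep(ix + 1, each = length(dy)))]
  dim(v11) <- dim(v21) <- dim(v12) <- dim(v22) <- c(length(dy), length(dx))
  out <- (1 - FX) * ((1 - FY) * v11 + FY * v21) +
    FX * ((1 - FY) * v12 + FY * v22)
  geo_grid(out[length(dy):1, , drop = FALSE], dst_geom)
}
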