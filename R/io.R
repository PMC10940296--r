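# Layer I/O and archive bookkeeping. Rasters are stored as ESRI ASCII grids
# (plain text, cell-center registered via xllcenter/yllcenter) so round-trips
# need no external geospatial libraries; 12-month stacks are one .asc file
# per month. Tables travel as CSV.

#' Write / read a grid as an ESRI ASCII raster
#'
#' Plain-text `.asc` format: 6 header lines then rows north to south.
#' `NA` is written as the declared `NODATA_value`.
#'
#' @param grid A [geo_grid()].
#' @param path Output file path.
#' @param digits Significant digits written (default 10; round-trips double
#'   precision to ~1e-9 relative).
#' @return `write_grid_ascii()`: `path`, invisibly. `read_grid_ascii()`:
#'   a `geo_grid`.
#' @export
write_grid_ascii <- function(grid, path, digits = 10) {
  stopifnot(inherits(grid, "geo_grid"))
  g <- grid$geom
  hdr <- c(
    sprintf("ncols %d", g$ncol),
    sprintf("nrows %d", g$nrow),
    sprintf("xllcenter %.10g", g$xmin + g$res / 2),
    sprintf("yllcenter %.10g", g$ymin + g$res / 2),
    sprintf("cellsize %.10g", g$res),
    "NODATA_value -9999")
  v <- grid$values
  storage.mode(v) <- "double"
  v[is.na(v)] <- -9999
  rows <- apply(v, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_grid_ascii
#' @export
read_grid_ascii <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  ncol <- as.integer(val[["ncols"]]); nrow <- as.integer(val[["nrows"]])
  res <- val[["cellsize"]]
  if ("xllcenter" %in% key) {
    xmin <- val[["xllcenter"]] - res / 2; ymin <- val[["yllcenter"]] - res / 2
  } else {
    xmin <- val[["xllcorner"]]; ymin <- val[["yllcorner"]]
  }
  nodata <- if ("nodata_value" %in% key) val[["nodata_value"]] else -9999
  geom <- grid_geometry(xmin, xmin + ncol * res, ymin, ymin + nrow * res, res)
  v <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"),
                   quiet = TRUE), nrow, ncol, byrow = TRUE)
  v[v == nodata] <- NA_real_
  geo_grid(v, geom)
}

#' Write / read a 12-month stack as per-month ASCII rasters
#'
#' Writes `<stem>_m01.asc` ... `<stem>_m12.asc`.
#'
#' @param arr `nrow x ncol x 12` array.
#' @param geom The shared [grid_geometry()].
#' @param stem Path stem (directory + file prefix).
#' @return `write_stack_ascii()`: the 12 paths, invisibly.
#'   `read_stack_ascii()`: `list(values = array, geom)`.
#' @export
write_stack_ascii <- function(arr, geom, stem) {
  stopifnot(is.array(arr), dim(arr)[3] == 12L)
  paths <- sprintf("%s_m%02d.asc", stem, 1:12)
  for (m in 1:12) write_grid_ascii(geo_grid(arr[, , m], geom), paths[m])
  invisible(paths)
}

#' @rdname write_stack_ascii
#' @export
read_stack_ascii <- function(stem) {
  paths <- sprintf("%s_m%02d.asc", stem, 1:12)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing stack layers: ",
                            paste(missing, collapse = ", "))
  g1 <- read_grid_ascii(paths[1])
  arr <- array(NA_real_, c(g1$geom$nrow, g1$geom$ncol, 12L))
  arr[, , 1] <- g1$values
  for (m in 2:12) arr[, , m] <- read_grid_ascii(paths[m])$values
  list(values = arr, geom = g1$geom)
}

# --- period / scenario vocabulary (archive Table-1 tokens) ----------------

PERIOD_TOKENS <- c("curr", "s126", "s370", "s585")
GCM_TOKENS <- c("cane", "cnrc", "cnrm", "erth", "gfdl",
                "ipsl", "miro", "mpie", "mrie", "uksm")
MODEL_TOKENS <- c(GCM_TOKENS, "mn")
CLASS_TOKENS <- c("Cereals", "Pulses", "Roots", "Banana")
DATATYPE_TOKENS <- c("suit", "suit_cl")

#' Period / scenario / model specification
#'
#' Validates the archive vocabulary: the historical period `curr`
#' (1984-2014, no model token) and the three future scenarios `s126`,
#' `s370`, `s585` (2035-2065), each requiring one of the 10 GCM tokens or
#' `mn` for the ensemble mean.
#'
#' @param label One of `"curr"`, `"s126"`, `"s370"`, `"s585"`.
#' @param model GCM token (or `"mn"`) for future labels; `NULL` for `curr`.
#' @return A `period_spec` list with `label`, `model`, `years`.
#' @export
period_spec <- function(label, model = NULL) {
  label <- match.arg(label, PERIOD_TOKENS)
  if (label == "curr") {
    if (!is.null(model)) stop("historical period 'curr' takes no model token")
    years <- c(1984L, 2014L)
  } else {
    if (is.null(model) || !model %in% MODEL_TOKENS)
      stop("future period '", label, "' requires a model token in {",
           paste(MODEL_TOKENS, collapse = ", "), "}")
    years <- c(2035L, 2065L)
  }
  structure(list(label = label, model = model, years = years),
            class = "period_spec")
}

#' Archive file name for a layer
#'
#' Builds `<class>_<crop>_<datatype>_<period>[_<model>].<ext>` following the
#' published archive convention (class, crop and period tokens of the data
#' descriptor's nomenclature table).
#'
#' @param crop_class One of Cereals, Pulses, Roots, Banana.
#' @param crop_code Crop token (validated against `registry` when given).
#' @param data_type `"suit"` (score) or `"suit_cl"` (binary class).
#' @param period Period token.
#' @param model Model token for future periods (10 GCM codes or `"mn"`).
#' @param ext File extension without dot; the published archive uses
#'   `"tif"`, this package's own writers use `"asc"`.
#' @param registry Optional [crop_registry] for crop-token validation.
#' @return Filename string.
#' @examples
#' archive_name("Cereals", "maize", "suit", "s370", "gfdl")
#' @export
archive_name <- function(crop_class, crop_code, data_type, period,
                         model = NULL, ext = "tif", registry = NULL) {
  if (!crop_class %in% CLASS_TOKENS) stop("invalid crop_class: ", crop_class)
  if (!data_type %in% DATATYPE_TOKENS) stop("invalid data_type: ", data_type)
  if (!period %in% PERIOD_TOKENS) stop("invalid period: ", period)
  if (!grepl("^[a-z]+$", crop_code)) stop("invalid crop_code: ", crop_code)
  if (!is.null(registry) && !crop_code %in% names(registry$entries))
    stop("invalid crop_code: ", crop_code)
  if (period == "curr") {
    if (!is.null(model)) stop("model token not allowed for period 'curr'")
    sprintf("%s_%s_%s_%s.%s", crop_class, crop_code, data_type, period, ext)
  } else {
    if (is.null(model) || !model %in% MODEL_TOKENS)
      stop("invalid model token: ", if (is.null(model)) "<missing>" else model)
    sprintf("%s_%s_%s_%s_%s.%s", crop_class, crop_code, data_type, period,
            model, ext)
  }
}

# --- temporal aggregation -------------------------------------------------

#' Aggregate daily series to monthly layers
#'
#' Precipitation is summed per month (mm); temperature is averaged (degC).
#' In strict mode a month missing any day is returned as `NA`; otherwise
#' months with coverage at least `min_coverage` are aggregated from the
#' available days (sums rescaled to the full month length).
#'
#' @param values Numeric vector of daily values for one cell-year (`NA` =
#'   missing day).
#' @param month_of_day Integer 1-12 assigning each entry to a month.
#' @param kind `"precipitation"` or `"temperature"`.
#' @param strict If `TRUE` (default), any missing day voids the month.
#' @param min_coverage Fraction of days required in tolerant mode.
#' @return Numeric vector of 12 monthly values.
#' @export
aggregate_to_monthly <- function(values, month_of_day,
                                 kind = c("precipitation", "temperature"),
                                 strict = TRUE, min_coverage = 0.9) {
  kind <- match.arg(kind)
  stopifnot(length(values) == length(month_of_day),
            all(month_of_day %in% 1:12))
  out <- rep(NA_real_, 12)
  for (m in 1:12) {
    v <- values[month_of_day == m]
    if (!length(v)) next
    nmiss <- sum(is.na(v))
    if (strict && nmiss > 0) next
    if (!strict && (length(v) - nmiss) / length(v) < min_coverage) next
    out[m] <- if (kind == "precipitation") {
      sum(v, na.rm = TRUE) * length(v) / (length(v) - nmiss)
    } else {
      mean(v, na.rm = TRUE)
    }
  }
  out
}

#' Multi-year monthly climatology
#'
#' Per calendar month, the arithmetic mean across the years of a period
#' (1984-2014 historical, 2035-2065 future).
#'
#' @param monthly Array `nrow x ncol x 12 x nyears` (or a list of
#'   `nrow x ncol x 12` arrays named by year).
#' @param years Integer vector of the years present, parallel to the last
#'   dimension.
#' @param period A [period_spec()]; every year in its range must be present.
#' @return `nrow x ncol x 12` climatology array.
#' @export
climatology <- function(monthly, years, period) {
  stopifnot(inherits(period, "period_spec"))
  if (is.list(monthly)) monthly <- simplify2array(monthly)
  need <- seq(period$years[1], period$years[2])
  missing <- setdiff(need, years)
  if (length(missing))
    stop("missing years for period ", period$label, ": ",
         paste(missing, collapse = ", "))
  sel <- match(need, years)
  apply(monthly[, , , sel, drop = FALSE], 1:3, mean)
}
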