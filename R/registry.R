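# Crop parameter registry: the 23-crop table of climatic/edaphic niche
# bounds the engine consumes. The packaged CSV carries representative
# default values (the published niche tables are not reproduced here);
# users substitute their own table via load_registry(path).

CROP_FIELDS <- c("crop_code", "crop_class", "gmin", "gmax", "ktmp",
                 "tmin", "topmin", "topmax", "tmax",
                 "rmin", "ropmin", "ropmax", "rmax",
                 "phmin", "phopmin", "phopmax", "phmax", "has_mapspam")

#' Construct one crop's niche parameter set
#'
#' Holds the trapezoidal niche bounds for one crop: mean-temperature
#' quadruple (`tmin <= topmin <= topmax <= tmax`, degC), seasonal rainfall
#' quadruple (mm over the growing window), soil pH quadruple, kill
#' temperature `ktmp` (degC, `<= tmin`) and growth-cycle length range
#' `gmin..gmax` (days, within 30..365).
#'
#' @param crop_code Lowercase crop token (e.g. `"maize"`, `"pmillet"`).
#' @param crop_class One of `"Cereals"`, `"Pulses"`, `"Roots"`, `"Banana"`.
#' @param gmin,gmax Growth-cycle length bounds, days.
#' @param ktmp Kill temperature, degC.
#' @param tmin,topmin,topmax,tmax Mean-temperature niche bounds, degC.
#' @param rmin,ropmin,ropmax,rmax Seasonal rainfall niche bounds, mm.
#' @param phmin,phopmin,phopmax,phmax Soil pH niche bounds.
#' @param has_mapspam Whether the crop exists in the MAPSPAM reference set.
#' @param validate Check invariants on construction (default `TRUE`).
#' @return A `crop_parameters` object.
#' @export
crop_parameters <- function(crop_code, crop_class, gmin, gmax, ktmp,
                            tmin, topmin, topmax, tmax,
                            rmin, ropmin, ropmax, rmax,
                            phmin, phopmin, phopmax, phmax,
                            has_mapspam = TRUE, validate = TRUE) {
  p <- structure(mget(setdiff(CROP_FIELDS, NULL)), class = "crop_parameters")
  p <- p[CROP_FIELDS]
  class(p) <- "crop_parameters"
  if (validate) {
    bad <- validate_parameters(p)
    if (length(bad))
      stop("invalid parameters for ", crop_code, ": ",
           paste(bad, collapse = "; "))
  }
  p
}

#' Check a parameter set against the niche-ordering invariants
#'
#' Returns descriptions of violated invariants rather than raising, so
#' loaders can report every problem in a table at once.
#'
#' @param p A [crop_parameters()] (or any list with the same fields).
#' @return Character vector of violations; empty if the set is valid.
#' @examples
#' p <- crop_parameters("demo", "Cereals", 90, 120, 0, 10, 15, 25, 30,
#'                      300, 500, 900, 1200, 5, 5.5, 7, 8)
#' validate_parameters(p)  # character(0)
#' @export
validate_parameters <- function(p) {
  v <- character(0)
  chk <- function(a, b) {
    if (!is.na(p[[a]]) && !is.na(p[[b]]) && p[[a]] > p[[b]])
      v <<- c(v, sprintf("%s <= %s violated (%g > %g)", a, b, p[[a]], p[[b]]))
  }
  num <- setdiff(CROP_FIELDS, c("crop_code", "crop_class", "has_mapspam"))
  for (f in num)
    if (!is.numeric(p[[f]]) || is.na(p[[f]]))
      v <- c(v, sprintf("%s is not a finite number", f))
  if (length(v)) return(v)
  chk("tmin", "topmin"); chk("topmin", "topmax"); chk("topmax", "tmax")
  chk("rmin", "ropmin"); chk("ropmin", "ropmax"); chk("ropmax", "rmax")
  chk("phmin", "phopmin"); chk("phopmin", "phopmax"); chk("phopmax", "phmax")
  chk("ktmp", "tmin")
  chk("gmin", "gmax")
  if (p$gmin < 30) v <- c(v, sprintf("30 <= gmin violated (%g)", p$gmin))
  if (p$gmax > 365) v <- c(v, sprintf("gmax <= 365 violated (%g)", p$gmax))
  if (!p$crop_class %in% CLASS_TOKENS)
    v <- c(v, sprintf("crop_class '%s' not in {%s}", p$crop_class,
                      paste(CLASS_TOKENS, collapse = ", ")))
  v
}

#' Load a crop parameter registry from CSV
#'
#' Reads a comma-separated, UTF-8, dot-decimal table with one row per crop
#' and a header naming every parameter field; unknown extra columns are
#' preserved and written back by [write_registry()]. Every row must pass
#' [validate_parameters()]; lookups by `crop_code` are case-sensitive.
#'
#' @param source Path to a CSV, or `NULL` for the packaged 23-crop default.
#' @return A `crop_registry`: `entries` (named list of `crop_parameters`),
#'   `table` (the raw data.frame), `class_counts`.
#' @examples
#' reg <- load_registry()
#' length(reg$entries)         # 23
#' reg$class_counts
#' @export
load_registry <- function(source = NULL) {
  if (is.null(source))
    source <- system.file("extdata", "crop_parameters.csv",
                          package = "cropsuit", mustWork = TRUE)
  tab <- utils::read.csv(source, stringsAsFactors = FALSE,
                         encoding = "UTF-8", check.names = FALSE)
  missing <- setdiff(CROP_FIELDS, names(tab))
  if (length(missing))
    stop("registry CSV is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tab$crop_code))
    stop("duplicate crop_code: ",
         paste(unique(tab$crop_code[duplicated(tab$crop_code)]), collapse = ", "))
  num <- setdiff(CROP_FIELDS, c("crop_code", "crop_class", "has_mapspam"))
  for (f in num)
    if (!is.numeric(tab[[f]]))
      stop("non-numeric value in column '", f, "'")
  tab$has_mapspam <- as.logical(tab$has_mapspam)
  entries <- lapply(seq_len(nrow(tab)), function(i) {
    p <- as.list(tab[i, CROP_FIELDS])
    p$has_mapspam <- as.logical(p$has_mapspam)
    class(p) <- "crop_parameters"
    bad <- validate_parameters(p)
    if (length(bad))
      stop("invalid parameters in row ", i, " (", tab$crop_code[i], "): ",
           paste(bad, collapse = "; "))
    p
  })
  names(entries) <- tab$crop_code
  structure(list(entries = entries, table = tab,
                 class_counts = table(tab$crop_class)),
            class = "crop_registry")
}

#' @export
print.crop_registry <- function(x, ...) {
  cat(sprintf("crop_registry: %d crops (%s); %d with MAPSPAM reference\n",
              length(x$entries),
              paste(sprintf("%s %d", names(x$class_counts), x$class_counts),
                    collapse = ", "),
              sum(vapply(x$entries, `[[`, TRUE, "has_mapspam"))))
  invisible(x)
}

#' Write a registry back to CSV
#'
#' Round-trips [load_registry()] bit-exactly for the packaged dialect
#' (comma separator, dot decimal, one header row), preserving any extra
#' columns present at load time.
#'
#' @param registry A `crop_registry`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "crop_registry"))
  utils::write.csv(registry$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up one crop's parameters
#'
#' @param registry A `crop_registry`.
#' @param crop_code Case-sensitive crop token.
#' @return A `crop_parameters` object.
#' @export
get_crop <- function(registry, crop_code) {
  p <- registry$entries[[crop_code]]
  if (is.null(p)) stop("unknown crop_code: ", crop_code)
  p
}
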