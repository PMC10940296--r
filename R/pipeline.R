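# Orchestration: run plans over crops x scenarios x GCMs, per-run layer
# writing under the archive naming convention, ensemble means, percent-
# suitable-area summaries, and a manifest accounting for every layer
# produced.

#' Enumerate the runs of a full production plan
#'
#' Per crop: one historical run plus one run per scenario x GCM, plus one
#' ensemble-mean aggregate per scenario. With the packaged defaults
#' (3 scenarios x 10 GCMs) that is 30 future model runs per crop.
#'
#' @param registry A [load_registry()] result.
#' @param scenarios Scenario tokens (default `s126`, `s370`, `s585`).
#' @param gcms GCM tokens (default the 10 packaged codes).
#' @return A data.frame (`crop_code`, `crop_class`, `period`, `model`,
#'   `kind` in {historical, future, ensemble_mean}) with attribute
#'   `counts`.
#' @examples
#' plan <- enumerate_runs(load_registry())
#' attr(plan, "counts")$future_per_crop  # 30
#' @export
enumerate_runs <- function(registry,
                           scenarios = c("s126", "s370", "s585"),
                           gcms = GCM_TOKENS) {
  bad <- setdiff(scenarios, setdiff(PERIOD_TOKENS, "curr"))
  if (length(bad)) stop("unknown scenario token(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(gcms, GCM_TOKENS)
  if (length(bad)) stop("unknown GCM token(s): ", paste(bad, collapse = ", "))
  crops <- names(registry$entries)
  cls <- vapply(registry$entries, `[[`, "", "crop_class")
  one <- function(cc) {
    rbind(
      data.frame(crop_code = cc, crop_class = cls[[cc]], period = "curr",
                 model = NA_character_, kind = "historical"),
      expand.grid(crop_code = cc, crop_class = cls[[cc]], period = scenarios,
                  model = gcms, kind = "future",
                  stringsAsFactors = FALSE),
      data.frame(crop_code = cc, crop_class = cls[[cc]], period = scenarios,
                 model = "mn", kind = "ensemble_mean"))
  }
  plan <- do.call(rbind, lapply(crops, one))
  rownames(plan) <- NULL
  attr(plan, "counts") <- list(
    crops = length(crops),
    scenarios = length(scenarios),
    gcms = length(gcms),
    future_per_crop = length(scenarios) * length(gcms),
    total_runs = nrow(plan),
    layers_total = 2L * nrow(plan))  # suit + suit_cl per run
  plan
}

#' Run one crop for one period and write its two layers
#'
#' Computes the suitability map, binarizes it with the calibrated
#' threshold, and writes both layers (`suit`, `suit_cl`) under the archive
#' naming convention; nothing is written if any input is missing.
#'
#' @param crop_code Crop token (must be in `registry`).
#' @param registry A [load_registry()] result.
#' @param stack A [climate_stack()] for the period.
#' @param ph Soil-pH `geo_grid`.
#' @param period Period token.
#' @param model Model token (`NULL` for `curr`).
#' @param threshold Calibrated binarization threshold.
#' @param outdir Output directory (created if needed).
#' @param cfg An [engine_config()].
#' @param params Optional calibrated [crop_parameters()] overriding the
#'   registry entry.
#' @return A two-row manifest data.frame (see [run_manifest()]).
#' @export
run_crop <- function(crop_code, registry, stack, ph, period, model = NULL,
                     threshold = 0.5, outdir = ".", cfg = engine_config(),
                     params = NULL) {
  p <- if (is.null(params)) get_crop(registry, crop_code) else params
  # fail before any write
  names2 <- vapply(DATATYPE_TOKENS, function(dt)
    archive_name(p$crop_class, crop_code, dt, period, model, ext = "asc"),
    "")
  map <- map_suitability(stack, ph, p, cfg, crop_code = crop_code,
                         period = period,
                         model = if (is.null(model)) NA_character_ else model)
  bin <- binarize(map, threshold)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, names2)
  write_grid_ascii(map, paths[1])
  write_grid_ascii(geo_grid(bin$values * 1, bin$geom), paths[2])
  data.frame(crop_code = crop_code, crop_class = p$crop_class,
             data_type = DATATYPE_TOKENS, period = period,
             model = if (is.null(model)) NA_character_ else model,
             filename = names2,
             checksum = as.character(tools::md5sum(paths)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run a scenario ensemble for one crop
#'
#' Runs the engine once per GCM climatology, writes per-GCM layers, then
#' the ensemble mean: the cell-wise arithmetic mean of the member
#' suitability scores (tagged `mn`), binarized with the same calibrated
#' threshold.
#'
#' @param crop_code Crop token.
#' @param registry A [load_registry()] result.
#' @param scenario Scenario token (`s126`, `s370` or `s585`).
#' @param gcm_stacks Named list of [climate_stack()]s, one per GCM token.
#' @param ph Soil-pH `geo_grid`.
#' @param threshold Calibrated threshold.
#' @param outdir Output directory.
#' @param cfg An [engine_config()].
#' @param params Optional calibrated parameters.
#' @param gcms GCM tokens required (default the packaged 10).
#' @return List: `manifest` (data.frame over all layers), `mean_map`
#'   (the ensemble-mean [suitability_map()]), `member_maps`.
#' @export
run_ensemble <- function(crop_code, registry, scenario, gcm_stacks, ph,
                         threshold = 0.5, outdir = ".",
                         cfg = engine_config(), params = NULL,
                         gcms = GCM_TOKENS) {
  missing <- setdiff(gcms, names(gcm_stacks))
  if (length(missing))
    stop("missing GCM climatologies: ", paste(missing, collapse = ", "))
  p <- if (is.null(params)) get_crop(registry, crop_code) else params
  rows <- list(); members <- list()
  for (g in gcms) {
    rows[[g]] <- run_crop(crop_code, registry, gcm_stacks[[g]], ph,
                          scenario, g, threshold, outdir, cfg, params = p)
    members[[g]] <- map_suitability(gcm_stacks[[g]], ph, p, cfg,
                                    crop_code = crop_code, period = scenario,
                                    model = g)
  }
  mean_vals <- Reduce(`+`, lapply(members, `[[`, "values")) / length(members)
  mean_map <- suitability_map(mean_vals, ph$geom, crop_code, scenario, "mn")
  mean_bin <- binarize(mean_map, threshold)
  nm <- vapply(DATATYPE_TOKENS, function(dt)
    archive_name(p$crop_class, crop_code, dt, scenario, "mn", ext = "asc"), "")
  paths <- file.path(outdir, nm)
  write_grid_ascii(mean_map, paths[1])
  write_grid_ascii(geo_grid(mean_bin$values * 1, mean_bin$geom), paths[2])
  rows$mn <- data.frame(crop_code = crop_code, crop_class = p$crop_class,
                        data_type = DATATYPE_TOKENS, period = scenario,
                        model = "mn", filename = nm,
                        checksum = as.character(tools::md5sum(paths)),
                        stringsAsFactors = FALSE, row.names = NULL)
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(manifest = manifest, mean_map = mean_map, member_maps = members)
}

#' Assemble and check a run manifest
#'
#' @param rows Data.frame(s) of layer descriptors as produced by
#'   [run_crop()] / [run_ensemble()].
#' @return The combined manifest; errors on duplicate filenames or names
#'   violating the archive convention.
#' @export
run_manifest <- function(rows) {
  m <- if (is.data.frame(rows)) rows else do.call(rbind, rows)
  if (anyDuplicated(m$filename))
    stop("duplicate layer filename(s): ",
         paste(unique(m$filename[duplicated(m$filename)]), collapse = ", "))
  pat <- sprintf("^(%s)_[a-z]+_(suit|suit_cl)_(%s)(_(%s))?\\.[a-z]+$",
                 paste(CLASS_TOKENS, collapse = "|"),
                 paste(PERIOD_TOKENS, collapse = "|"),
                 paste(MODEL_TOKENS, collapse = "|"))
  bad <- m$filename[!grepl(pat, m$filename)]
  if (length(bad))
    stop("filename(s) violate the archive convention: ",
         paste(bad, collapse = ", "))
  rownames(m) <- NULL
  m
}

#' Area-weighted percent of land suitable
#'
#' `100 * suitable area / land area`, both sums weighted by spherical cell
#' areas (an unweighted cell fraction would over-count high latitudes).
#'
#' @param binary Logical `geo_grid`.
#' @param land_mask Logical matrix of land cells on the same geometry.
#' @return Percent in `[0, 100]`.
#' @export
percent_suitable_area <- function(binary, land_mask = NULL) {
  stopifnot(inherits(binary, "geo_grid"))
  if (is.null(land_mask)) land_mask <- !is.na(binary$values)
  if (!any(land_mask)) stop("empty land mask")
  area <- cell_area_grid(binary$geom)
  suit <- !is.na(binary$values) & binary$values & land_mask
  100 * sum(area[suit]) / sum(area[land_mask])
}

#' Ensemble spread of percent-suitable values
#'
#' @param percents Per-GCM percent-suitable values (>= 2).
#' @return List `mean`, `min`, `max`.
#' @export
summarize_ensemble_spread <- function(percents) {
  if (length(percents) < 2) stop("need at least 2 ensemble members")
  list(mean = mean(percents), min = min(percents), max = max(percents))
}
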