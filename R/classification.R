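# Binary reference construction, sensitivity-specificity-equalized
# thresholding, and the iterative rainfall/temperature calibration loop
# that widens a crop's niche until the binary map reaches the target match
# with the yield-derived reference.

#' Binary reference from a yield grid
#'
#' Cells below the given percentile of positive yields are labelled
#' unsuitable; the percentile is computed over positive-yield cells only
#' (linear interpolation between order statistics). Cells with yield 0 are
#' unsuitable; the evaluation mask covers every cell where yield is
#' defined.
#'
#' @param yield A `geo_grid` of non-negative yields (`NA` = outside mask).
#' @param percentile Percentile of positive yields used as the cut
#'   (default 25).
#' @return A `reference_grid`: `labels` (logical matrix, TRUE = suitable),
#'   `mask` (logical matrix), `cutoff` (the yield value used), `geom`.
#' @export
reference_from_yield <- function(yield, percentile = 25) {
  stopifnot(inherits(yield, "geo_grid"))
  y <- yield$values
  if (any(y < 0, na.rm = TRUE)) stop("yields must be non-negative")
  pos <- y[!is.na(y) & y > 0]
  if (!length(pos)) stop("no positive-yield cell to take the percentile over")
  cutoff <- as.numeric(stats::quantile(pos, percentile / 100, type = 7))
  labels <- !is.na(y) & y >= cutoff
  labels[is.na(y)] <- NA
  structure(list(labels = labels, mask = !is.na(y), cutoff = cutoff,
                 geom = yield$geom), class = "reference_grid")
}

#' Sensitivity and specificity at a threshold
#'
#' Predictions are `score >= threshold`. `Se = TP/(TP+FN)`,
#' `Sp = TN/(TN+FP)`.
#'
#' @param scores Numeric vector of scores.
#' @param labels Logical vector of reference labels (TRUE = suitable).
#' @param threshold Decision threshold.
#' @return Named vector `c(se =, sp =)`.
#' @export
confusion_rates <- function(scores, labels, threshold) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0)
    stop("both classes must be present to compute Se and Sp")
  pred <- scores >= threshold
  c(se = sum(pred & labels) / npos, sp = sum(!pred & !labels) / nneg)
}

#' Threshold equalizing sensitivity and specificity
#'
#' Scans every candidate threshold (the sorted unique scores plus 0 and 1 —
#' Se and Sp are step functions of the threshold, so this set contains the
#' exact optimum) and returns the one minimizing `|Se - Sp|`. Ties are
#' broken by larger `Se + Sp`, then by the smaller threshold.
#'
#' @inheritParams confusion_rates
#' @return A `threshold_result`: `threshold`, `se`, `sp`, `gap`,
#'   `n_candidates`.
#' @export
equalize_se_sp <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.logical(labels[keep])
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0)
    stop("both classes must be present to equalize Se and Sp")
  cand <- sort(unique(c(0, 1, scores)))
  # counts strictly below each candidate, via one sort
  ord <- order(scores)
  ss <- scores[ord]; ll <- labels[ord]
  below <- findInterval(cand, ss, left.open = TRUE)  # scores < cand... see below
  # findInterval(x, v) counts v <= x; with left.open=TRUE counts v < x
  cum_pos <- cumsum(ll)
  fn <- ifelse(below > 0, cum_pos[pmax(below, 1)], 0)
  fn[below == 0] <- 0
  tn <- below - fn
  se <- 1 - fn / npos
  sp <- tn / nneg
  gap <- abs(se - sp)
  # tolerance-based tie-breaking: minimal gap, then maximal Se + Sp, then
  # the smallest threshold (float-exact comparisons would make the winner
  # depend on rounding noise)
  tol <- 1e-12
  in_gap <- which(gap <= min(gap) + tol)
  in_sum <- in_gap[se[in_gap] + sp[in_gap] >=
                     max(se[in_gap] + sp[in_gap]) - tol]
  best <- in_sum[which.min(cand[in_sum])]
  structure(list(threshold = cand[best], se = se[best], sp = sp[best],
                 gap = gap[best], n_candidates = length(cand)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold %.4f: Se %.3f, Sp %.3f, |Se-Sp| %.4f (%d candidates)\n",
              x$threshold, x$se, x$sp, x$gap, x$n_candidates))
  invisible(x)
}

#' Binarize a suitability map
#'
#' @param map A `suitability_map` (or any `geo_grid`).
#' @param threshold Threshold in `[0, 1]`; cells with score `>= threshold`
#'   (boundary inclusive) are suitable. `NA` propagates.
#' @return A logical `geo_grid`; metadata copied when present.
#' @export
binarize <- function(map, threshold) {
  stopifnot(inherits(map, "geo_grid"), threshold >= 0, threshold <= 1)
  out <- geo_grid(map$values >= threshold, map$geom)
  out$meta <- map$meta
  out
}

#' Overall accuracy against a reference grid
#'
#' Proportion of evaluation-mask cells where the binary prediction equals
#' the reference label.
#'
#' @param binary Logical `geo_grid` of predictions.
#' @param reference A `reference_grid` from [reference_from_yield()].
#' @return Proportion in `[0, 1]`.
#' @export
match_score <- function(binary, reference) {
  stopifnot(inherits(binary, "geo_grid"), inherits(reference, "reference_grid"))
  if (!same_geometry(binary$geom, reference$geom))
    stop("prediction and reference geometries differ")
  m <- reference$mask & !is.na(binary$values)
  if (!any(m)) stop("empty evaluation mask")
  mean(binary$values[m] == reference$labels[m])
}

# one calibration evaluation: engine -> equalized threshold -> accuracy
eval_params <- function(p, stack, ph, reference, cfg) {
  map <- map_suitability(stack, ph, p, cfg)
  sc <- as.vector(map$values)
  lb <- as.vector(reference$labels)
  ok <- as.vector(reference$mask) & !is.na(sc)
  th <- equalize_se_sp(sc[ok], lb[ok])
  bin <- binarize(map, th$threshold)
  list(match = match_score(bin, reference), threshold = th$threshold,
       se = th$se, sp = th$sp, map = map)
}

#' Iterative rainfall calibration
#'
#' Decrements the rainfall minima (`rmin`, `ropmin`) in fixed steps —
#' widening the niche toward drier conditions — re-running the engine,
#' re-equalizing the threshold and re-scoring after each step, until the
#' match target is reached or both minima hit the floor. If the target is
#' never reached the best-scoring state is retained.
#'
#' @param p Starting [crop_parameters()].
#' @param stack A [climate_stack()].
#' @param ph Soil-pH `geo_grid`.
#' @param reference A `reference_grid`.
#' @param step Decrement per iteration, mm (default 10).
#' @param target Match-score convergence criterion (default 0.7).
#' @param floor Lower bound for the rainfall minima, mm (default 0).
#' @param cfg An [engine_config()].
#' @return List with `params` (calibrated), `trace` (data.frame: iteration,
#'   rmin, ropmin, threshold, match), `status`
#'   (`"converged"`/`"retained_best"`), `threshold`, `match`.
#' @export
calibrate_rainfall <- function(p, stack, ph, reference, step = 10,
                               target = 0.7, floor = 0,
                               cfg = engine_config()) {
  stopifnot(step > 0)
  bad <- validate_parameters(p)
  if (length(bad)) stop("invalid starting parameters: ",
                        paste(bad, collapse = "; "))
  states <- list(); i <- 0L; cur <- p
  repeat {
    ev <- eval_params(cur, stack, ph, reference, cfg)
    states[[length(states) + 1L]] <-
      list(iteration = i, params = cur, threshold = ev$threshold,
           match = ev$match)
    if (ev$match >= target) { status <- "converged"; break }
    if (cur$rmin <= floor && cur$ropmin <= floor) {
      status <- "retained_best"; break
    }
    cur$rmin <- max(floor, cur$rmin - step)
    cur$ropmin <- max(cur$rmin, max(floor, cur$ropmin - step))
    i <- i + 1L
  }
  trace <- do.call(rbind, lapply(states, function(s)
    data.frame(iteration = s$iteration, rmin = s$params$rmin,
               ropmin = s$params$ropmin, threshold = s$threshold,
               match = s$match)))
  pick <- if (status == "converged") length(states) else
    which.max(trace$match)
  list(params = states[[pick]]$params, trace = trace, status = status,
       threshold = states[[pick]]$threshold, match = states[[pick]]$match)
}

#' Temperature-niche calibration by bounded grid search
#'
#' Searches kill-temperature and temperature-niche offsets over
#' `offsets x offsets` (default -5..+5 degC in 1 degC steps), the niche
#' offset shifting `tmin`, `topmin`, `topmax`, `tmax` as a rigid block.
#' Candidates are visited in order of increasing total displacement
#' `|k| + |n|` (so the identity (0, 0) is evaluated first) and the search
#' stops at the first state reaching the match target; if none does, the
#' best-scoring state is retained.
#'
#' @inheritParams calibrate_rainfall
#' @param offsets Integer offsets tried for each of the two parameters,
#'   degC.
#' @return As [calibrate_rainfall()], with trace columns `ktmp_offset`,
#'   `niche_offset`; plus `ktmp_offset`, `niche_offset` of the returned
#'   state.
#' @export
calibrate_temperature <- function(p, stack, ph, reference,
                                  offsets = -5:5, target = 0.7,
                                  cfg = engine_config()) {
  bad <- validate_parameters(p)
  if (length(bad)) stop("invalid starting parameters: ",
                        paste(bad, collapse = "; "))
  grid <- expand.grid(ktmp_offset = offsets, niche_offset = offsets)
  grid <- grid[order(abs(grid$ktmp_offset) + abs(grid$niche_offset),
                     pmax(abs(grid$ktmp_offset), abs(grid$niche_offset)),
                     abs(grid$ktmp_offset), grid$ktmp_offset,
                     grid$niche_offset), ]
  rows <- list(); found <- NULL
  for (j in seq_len(nrow(grid))) {
    ko <- grid$ktmp_offset[j]; no <- grid$niche_offset[j]
    cand <- p
    cand$ktmp <- p$ktmp + ko
    for (f in c("tmin", "topmin", "topmax", "tmax"))
      cand[[f]] <- p[[f]] + no
    ev <- eval_params(cand, stack, ph, reference, cfg)
    rows[[j]] <- data.frame(iteration = j - 1L, ktmp_offset = ko,
                            niche_offset = no, threshold = ev$threshold,
                            match = ev$match)
    if (ev$match >= target) { found <- j; break }
  }
  trace <- do.call(rbind, rows)
  status <- if (!is.null(found)) "converged" else "retained_best"
  pick <- if (!is.null(found)) found else which.max(trace$match)
  best <- p
  best$ktmp <- p$ktmp + trace$ktmp_offset[pick]
  for (f in c("tmin", "topmin", "topmax", "tmax"))
    best[[f]] <- p[[f]] + trace$niche_offset[pick]
  list(params = best, trace = trace, status = status,
       threshold = trace$threshold[pick], match = trace$match[pick],
       ktmp_offset = trace$ktmp_offset[pick],
       niche_offset = trace$niche_offset[pick])
}

#' Write a calibration trace to CSV
#'
#' @param result A result from [calibrate_rainfall()] or
#'   [calibrate_temperature()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calibration_trace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
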