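#' Pixel-level population density weighting layer
#'
#' Applies the fitted forest to every valid pixel's covariate values and
#' exponentiates the predicted log density into a strictly positive
#' density weight; nodata pixels get weight 0.  The forest is trained on
#' zonal summaries and applied to pixel values — the scale mismatch is
#' inherent to this dasymetric method and deliberate.
#'
#' @param model a `pop_forest` or `pop_model`.
#' @param stack a [covariate_stack()] providing every covariate of the
#'   final model.
#' @return numeric matrix of density weights (0 at nodata pixels).
#' @export
predict_weight_grid <- function(model, stack) {
  if (inherits(model, "pop_model")) model <- model$forest
  stopifnot(inherits(model, "pop_forest"), inherits(stack, "covariate_stack"))
  pd <- pixel_design(stack, model$covariates)
  pred <- rowMeans(predict_forest_all_cpp(model$trees, pd$X))
  w <- matrix(0, stack$nrow, stack$ncol)
  w[pd$valid] <- exp(pred)
  w
}

#' Dasymetric redistribution of census counts
#'
#' Distributes each unit's census count over its pixels proportionally to
#' the weighting layer: `pop = count * w / sum(w in zone)`.  Zones whose
#' weights sum to zero fall back to uniform allocation over their valid
#' pixels, so per-zone mass conservation holds for every input.
#'
#' @param weights non-negative weight matrix (e.g. from
#'   [predict_weight_grid()]).
#' @param zones a [zone_map()] aligned with `weights`.
#' @param census data.frame with `unit_id` and `count` covering the zones.
#' @return matrix of people per pixel (`NA` outside any zone) with the
#'   census totals preserved per zone.
#' @export
dasymetric_redistribute <- function(weights, zones, census) {
  if (!identical(dim(weights), dim(zones)))
    stop_config("weights and zone map are not aligned")
  if (any(census$count < 0)) stop_config("negative census counts")
  zl <- unique(zones[!is.na(zones)])
  missing <- setdiff(census$unit_id, zl)
  if (length(missing))
    stop_config("census unit(s) absent from the zone map: ",
                paste(missing, collapse = ", "))
  pop <- matrix(NA_real_, nrow(zones), ncol(zones))
  for (i in seq_len(nrow(census))) {
    z <- census$unit_id[i]
    px <- which(!is.na(zones) & zones == z)
    w <- weights[px]
    s <- sum(w)
    pop[px] <- if (s > 0) census$count[i] * w / s
               else census$count[i] / length(px)
  }
  pop
}
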