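#' Random-forest dasymetric population model
#'
#' The package's central fitting function.  Implements the three-step
#' dasymetric procedure: (i) iterative covariate selection — repeated
#' forest fits with OOB permutation importance, dropping every covariate
#' with negative Per.Inc.m.s.e.; (ii) a final regression forest on the
#' retained zonal covariate summaries with log population density as the
#' response; (iii) prediction of a pixel-level density weighting layer
#' used to redistribute the census counts onto the grid (see
#' [predict.pop_model()]).
#'
#' @param stack a [covariate_stack()].
#' @param zones a [zone_map()] aligned with the stack.
#' @param census data.frame with `unit_id` and `count` for every zone.
#' @param ntree,mtry,nodesize forest parameters, see [fit_forest()].
#' @param select run iterative covariate selection first (default `TRUE`).
#' @param density_floor additive density floor inside the log response.
#' @param seed master seed; selection iterations, the final fit and the
#'   final importance permutations all derive their seeds from it.
#' @return an object of class `pop_model` with components `forest`
#'   (the final [fit_forest()] object), `importance` (final
#'   Per.Inc.m.s.e. table), `trace` (the [iterative_covariate_selection()]
#'   trace, or `NULL`), `table` (the [zonal_table()]), and the inputs.
#' @seealso [predict.pop_model()], [summary.pop_model()],
#'   [dasymetric_redistribute()]
#' @examples
#' cty <- generate_country(landscape_null(seed = 7))
#' fit <- pop_model(cty$stack, cty$zones, cty$census, ntree = 50, seed = 1)
#' summary(fit)
#' pop <- predict(fit, type = "population")
#' @export
pop_model <- function(stack, zones, census, ntree = 500, mtry = NULL,
                      nodesize = 5, select = TRUE, density_floor = 1e-8,
                      seed = NULL) {
  tab <- zonal_table(stack, zones, census, density_floor = density_floor)
  seeds <- derive_seeds(seed, 3L)
  trace <- NULL
  covs <- attr(tab, "covariates")
  if (select) {
    trace <- iterative_covariate_selection(tab, ntree = ntree, mtry = mtry,
                                           nodesize = nodesize,
                                           seed = seeds[1L])
    covs <- trace$final_covariates
  }
  forest <- fit_forest(as.data.frame(tab)[, covs, drop = FALSE],
                       tab$response, ntree = ntree, mtry = mtry,
                       nodesize = nodesize, seed = seeds[2L])
  imp <- oob_permutation_importance(forest, seed = seeds[3L])
  structure(list(forest = forest, importance = imp, trace = trace,
                 table = tab, stack = stack, zones = zones, census = census,
                 density_floor = density_floor, seed = seed,
                 call = match.call()),
            class = "pop_model")
}

#' @export
print.pop_model <- function(x, ...) {
  cat("Random-forest dasymetric population model\n")
  cat(sprintf("  %d admin units, %d candidate -> %d final covariates\n",
              nrow(x$table), length(attr(x$table, "covariates")),
              length(x$forest$covariates)))
  print(x$forest)
  invisible(x)
}

#' Summarize a fitted population model
#'
#' @param object a `pop_model`.
#' @param ... unused.
#' @return an object of class `summary.pop_model`: number of trees, OOB
#'   m.s.e., variance explained (per cent), final covariates with their
#'   Per.Inc.m.s.e., and the number of selection iterations.
#' @export
summary.pop_model <- function(object, ...) {
  structure(list(n_units = nrow(object$table),
                 ntree = object$forest$ntree,
                 oob_mse = object$forest$oob_mse,
                 variance_explained = object$forest$variance_explained,
                 n_iterations = if (is.null(object$trace)) 0L
                                else length(object$trace$steps),
                 importance = object$importance),
            class = "summary.pop_model")
}

#' @export
print.summary.pop_model <- function(x, ...) {
  cat(sprintf("units: %d   trees: %d   selection iterations: %d\n",
              x$n_units, x$ntree, x$n_iterations))
  cat(sprintf("OOB m.s.e.: %.4g   variance explained: %s\n", x$oob_mse,
              if (is.na(x$variance_explained)) "undefined"
              else sprintf("%.1f%%", x$variance_explained)))
  print(x$importance)
  invisible(x)
}

#' Predict a weighting layer or population grid from a fitted model
#'
#' @param object a `pop_model`.
#' @param type `"weights"` for the pixel density weighting layer (positive
#'   on valid pixels, 0 at nodata), `"population"` for the dasymetric
#'   people-per-pixel grid whose per-zone sums equal the census counts.
#' @param stack covariate stack to predict on (defaults to the training
#'   stack).
#' @param zones,census zoning and counts for the redistribution (default:
#'   training inputs).
#' @param ... unused.
#' @return numeric matrix.
#' @export
predict.pop_model <- function(object, type = c("weights", "population"),
                              stack = NULL, zones = NULL, census = NULL,
                              ...) {
  type <- match.arg(type)
  stack <- stack %||% object$stack
  w <- predict_weight_grid(object$forest, stack)
  if (type == "weights") return(w)
  dasymetric_redistribute(w, zones %||% object$zones,
                          census %||% object$census)
}

#' @export
residuals.pop_model <- function(object, ...) {
  object$table$response - object$forest$oob_pred
}

#' @export
fitted.pop_model <- function(object, ...) object$forest$oob_pred

#' Importance dot chart of a fitted population model
#'
#' @param x a `pop_model`.
#' @param ... passed to [graphics::dotchart()].
#' @export
plot.pop_model <- function(x, ...) {
  imp <- x$importance[order(x$importance$per_inc_mse), ]
  dotchart(imp$per_inc_mse, labels = imp$covariate,
           xlab = "Per.Inc.m.s.e. (%)", ...)
  abline(v = 0, lty = 2)
  invisible(x)
}

#' Model summary as a JSON-ready list
#'
#' Mirrors the per-country model summary files of the mapping workflow:
#' tree count, OOB error, variance explained and the final covariates with
#' their importance.
#'
#' @param model a `pop_model`.
#' @param path optional path; when given, the summary is written as JSON.
#' @return the summary list, invisibly when written.
#' @export
model_summary <- function(model, path = NULL) {
  stopifnot(inherits(model, "pop_model"))
  s <- list(ntree = model$forest$ntree,
            mtry = model$forest$mtry,
            n_units = nrow(model$table),
            oob_mse = model$forest$oob_mse,
            variance_explained = model$forest$variance_explained,
            n_selection_iterations = if (is.null(model$trace)) 0L
                                     else length(model$trace$steps),
            final_covariates = model$forest$covariates,
            importance = as.data.frame(model$importance))
  if (!is.null(path)) {
    jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(s))
  }
  s
}
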