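#' Iterative covariate selection by negative OOB importance
#'
#' Repeats fit -> OOB permutation importance -> drop every covariate with
#' negative Per.Inc.m.s.e., until no covariate is negative or a single
#' covariate remains.  If all importances in an iteration are negative,
#' the single best covariate is retained (floor rule).  Fresh seeds for
#' each iteration's fit and permutations are derived deterministically
#' from the master seed.
#'
#' @param x covariate table (data.frame/matrix) or a [zonal_table()].
#' @param y response (ignored when `x` is a `zonal_table`).
#' @inheritParams fit_forest
#' @param seed master seed for the whole selection loop.
#' @return an object of class `selection_trace`: a list with one record
#'   per iteration (`iteration`, `covariates`, `importance`, `oob_mse`,
#'   `variance_explained`), plus `final_covariates` and `final_fit`.
#' @export
iterative_covariate_selection <- function(x, y = NULL, ntree = 500,
                                          mtry = NULL, nodesize = 5,
                                          seed = NULL) {
  if (inherits(x, "zonal_table")) {
    y <- x$response
    x <- x[, attr(x, "covariates"), drop = FALSE]
  }
  X <- as.data.frame(x)
  if (ncol(X) < 1L) stop_config("empty covariate table")
  covs <- colnames(X)
  max_iter <- length(covs) + 1L
  seeds <- matrix(derive_seeds(seed, 2L * max_iter), ncol = 2L)
  steps <- list()
  fit <- NULL
  for (it in seq_len(max_iter)) {
    fit <- fit_forest(X[, covs, drop = FALSE], y, ntree = ntree,
                      mtry = mtry, nodesize = nodesize,
                      seed = seeds[it, 1L])
    imp <- oob_permutation_importance(fit, seed = seeds[it, 2L])
    steps[[it]] <- list(iteration = it, covariates = covs,
                        importance = imp, oob_mse = fit$oob_mse,
                        variance_explained = fit$variance_explained)
    if (length(covs) == 1L) break
    neg <- imp$per_inc_mse < 0
    if (!any(neg)) break
    keep <- imp$covariate[!neg]
    if (length(keep) == 0L) {  # all negative: keep the least bad, stop
      covs <- imp$covariate[which.max(imp$per_inc_mse)]
      fit <- fit_forest(X[, covs, drop = FALSE], y, ntree = ntree,
                        mtry = mtry, nodesize = nodesize,
                        seed = seeds[it, 1L])
      steps[[it + 1L]] <- list(
        iteration = it + 1L, covariates = covs,
        importance = oob_permutation_importance(fit, seed = seeds[it, 2L]),
        oob_mse = fit$oob_mse,
        variance_explained = fit$variance_explained)
      break
    }
    covs <- keep
  }
  structure(list(steps = steps, final_covariates = covs, final_fit = fit),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("selection_trace: %d iteration(s)\n", length(x$steps)))
  for (s in x$steps)
    cat(sprintf("  iter %d: %d covariate(s), OOB m.s.e. %.4g\n",
                s$iteration, length(s$covariates), s$oob_mse))
  cat("  final:", paste(x$final_covariates, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.selection_trace <- function(x, ...) {
  do.call(rbind, lapply(x$steps, function(s) {
    data.frame(iteration = s$iteration, covariate = s$importance$covariate,
               per_inc_mse = s$importance$per_inc_mse,
               n_trees_used = s$importance$n_trees_used)
  }))
}
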