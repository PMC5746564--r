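#' Fit a bagged regression forest on zonal summaries
#'
#' Grows `ntree` unpruned CART regression trees, each on an independent
#' bootstrap resample (n draws with replacement) of the admin units, with
#' `mtry` randomly subsampled candidate variables per node.  The roughly
#' one third of units left out of a tree's bootstrap sample form its
#' out-of-bag (OOB) set; the model's `oob_mse` is the average over trees
#' of the per-tree OOB mean squared error, and
#' `variance_explained = 100 * (1 - oob_mse / var(response))` (population
#' variance) is the forest's pseudo-R^2 in per cent (may be negative).
#'
#' @param x data.frame or matrix of unit-level covariate summaries, or a
#'   [zonal_table()] (in which case `y` is taken from its response).
#' @param y numeric response (log population density per unit).
#' @param ntree number of trees.
#' @param mtry candidate variables per split; default `max(1, floor(p/3))`,
#'   the standard regression-forest default.
#' @param nodesize minimum terminal-node size.
#' @param seed RNG seed (bootstrap + split sampling).
#' @return an object of class `pop_forest`.
#' @export
fit_forest <- function(x, y = NULL, ntree = 500, mtry = NULL, nodesize = 5,
                       seed = NULL) {
  if (inherits(x, "zonal_table")) {
    y <- x$response
    x <- x[, attr(x, "covariates"), drop = FALSE]
  }
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (p < 1L) stop_config("at least one covariate is required")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (n < max(5L, nodesize))
    stop_config("too few units (", n, ") to fit a forest with nodesize ",
                nodesize)
  if (length(y) != n || any(!is.finite(y)))
    stop_config("response must be finite and match the number of units")
  if (anyNA(X)) stop_config("covariate table contains missing values")
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  if (!is.null(seed)) set.seed(seed)
  inbag <- vapply(seq_len(ntree),
                  function(b) tabulate(sample.int(n, n, replace = TRUE), n),
                  integer(n))
  trees <- grow_forest_cpp(X, y, inbag, as.integer(mtry),
                           as.integer(nodesize))

  # per-tree OOB error and ensemble OOB predictions
  tree_oob_mse <- rep(NA_real_, ntree)
  pred_sum <- numeric(n); pred_n <- integer(n)
  for (b in seq_len(ntree)) {
    oob <- which(inbag[, b] == 0L)
    if (length(oob) == 0L) next
    pb <- predict_tree_cpp(trees[[b]], X[oob, , drop = FALSE])
    tree_oob_mse[b] <- mean((y[oob] - pb)^2)
    pred_sum[oob] <- pred_sum[oob] + pb
    pred_n[oob] <- pred_n[oob] + 1L
  }
  oob_pred <- ifelse(pred_n > 0L, pred_sum / pmax(pred_n, 1L), NA_real_)
  oob_mse <- mean(tree_oob_mse, na.rm = TRUE)
  vy <- mean((y - mean(y))^2)  # population variance
  degenerate <- vy == 0
  ve <- if (degenerate) NA_real_ else 100 * (1 - oob_mse / vy)

  var_used <- matrix(FALSE, ntree, p, dimnames = list(NULL, colnames(X)))
  for (b in seq_len(ntree)) {
    s <- trees[[b]]$var
    var_used[b, unique(s[s >= 0L] + 1L)] <- TRUE
  }

  structure(list(trees = trees, inbag = inbag, x = X, y = y,
                 covariates = colnames(X), ntree = ntree, mtry = mtry,
                 nodesize = nodesize, tree_oob_mse = tree_oob_mse,
                 oob_mse = oob_mse, oob_pred = oob_pred,
                 response_variance = vy, degenerate = degenerate,
                 variance_explained = ve, var_used = var_used),
            class = "pop_forest")
}

#' @export
print.pop_forest <- function(x, ...) {
  cat(sprintf("pop_forest: %d trees, %d units, %d covariates (mtry %d, nodesize %d)\n",
              x$ntree, nrow(x$x), length(x$covariates), x$mtry, x$nodesize))
  cat(sprintf("  OOB m.s.e. (tree-averaged): %.4g\n", x$oob_mse))
  if (x$degenerate)
    cat("  variance explained: undefined (constant response)\n")
  else
    cat(sprintf("  variance explained: %.1f%%\n", x$variance_explained))
  invisible(x)
}

#' Predict from a fitted forest
#'
#' @param object a `pop_forest`.
#' @param newdata matrix or data.frame containing the model's covariate
#'   columns; defaults to the training table.
#' @param ... unused.
#' @return numeric vector of ensemble-mean predictions on the response
#'   (log-density) scale.
#' @export
predict.pop_forest <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$x else {
    nd <- as.matrix(as.data.frame(newdata)[, object$covariates, drop = FALSE])
    storage.mode(nd) <- "double"
    nd
  }
  rowMeans(predict_forest_all_cpp(object$trees, X))
}

#' Variance explained by a fitted forest
#'
#' `100 * (1 - oob_mse / var(response))` in per cent, where `oob_mse` is
#' the tree-averaged out-of-bag mean squared error.  Negative when the
#' forest predicts worse than the response mean; `NA` (with a message) for
#' a constant response.
#'
#' @param model a `pop_forest` or `pop_model`.
#' @return scalar percentage (may be negative), `NA` if the response
#'   variance is zero.
#' @export
variance_explained <- function(model) {
  if (inherits(model, "pop_model")) model <- model$forest
  stopifnot(inherits(model, "pop_forest"))
  if (model$degenerate)
    message("constant response: variance explained is undefined")
  model$variance_explained
}

#' Out-of-bag permutation importance (Per.Inc.m.s.e.)
#'
#' For every tree that used a covariate as a split variable, the
#' covariate's values are randomly permuted within that tree's OOB set and
#' the tree's OOB MSE recomputed; the covariate's importance is
#' `100 * mean((e_perm - e_oob) / e_oob)` over those trees — the average
#' per cent increase in MSE.  A covariate used by no tree scores exactly 0.
#' Trees whose OOB set has fewer than two units, or whose baseline OOB MSE
#' is zero, are skipped for that covariate.
#'
#' @param model a `pop_forest`.
#' @param seed RNG seed for the permutations.
#' @param detail if `TRUE`, attach a per-(tree, covariate) record table
#'   (baseline error, permuted error, permutation) as attribute
#'   `"detail"` — used for exhaustive small-instance verification.
#' @return data.frame of class `importance_table` with columns
#'   `covariate`, `per_inc_mse`, `n_trees_used`.
#' @export
oob_permutation_importance <- function(model, seed = NULL, detail = FALSE) {
  stopifnot(inherits(model, "pop_forest"))
  if (!is.null(seed)) set.seed(seed)
  res <- oob_importance_cpp(model$trees, model$x, model$y, model$inbag,
                            model$var_used, detail)
  if (res$n_small_oob > 0L)
    warning(sprintf("%d tree(s) skipped: OOB set smaller than 2 units",
                    res$n_small_oob))
  per_inc <- ifelse(res$n_ratio > 0L, 100 * res$sum_ratio / res$n_ratio, 0)
  out <- data.frame(covariate = model$covariates, per_inc_mse = per_inc,
                    n_trees_used = res$n_used, row.names = NULL)
  class(out) <- c("importance_table", "data.frame")
  if (detail) {
    d <- res$detail
    attr(out, "detail") <- data.frame(
      tree = d$tree, covariate = model$covariates[d$covariate],
      e_oob = d$e_oob, e_perm = d$e_perm,
      perm = I(d$perm))
  }
  out
}

#' @export
print.importance_table <- function(x, ...) {
  cat("OOB permutation importance (Per.Inc.m.s.e., %):\n")
  o <- order(-x$per_inc_mse)
  print.data.frame(data.frame(x)[o, , drop = FALSE], row.names = FALSE,
                   digits = 4)
  invisible(x)
}
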